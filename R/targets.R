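#' Find seed matches of a miRNA in a 3'UTR
#'
#' The seed is miRNA positions 2-8 (1-based from the 5' end); a site requires
#' the perfect Watson-Crick reverse complement of the seed in the UTR (no G:U
#' in the seed).
#'
#' @param mirna miRNA sequence (RNA or DNA), length at least 8.
#' @param utr UTR sequence.
#' @return integer vector of 1-based UTR start positions of the 7-nt seed
#'   complement (empty when the UTR is shorter than 7).
#' @export
find_seed_matches <- function(mirna, utr) {
  mirna <- normalize_dna(mirna); utr <- normalize_dna(utr)
  .stop_if(nchar(mirna) < 8L, "miRNA must be at least 8 nt")
  if (nchar(utr) < 7L) return(integer(0))
  seed_rc <- revcomp(substr(mirna, 2L, 8L))
  m <- Biostrings::matchPattern(seed_rc, Biostrings::DNAString(utr),
                                max.mismatch = 0L)
  as.integer(BiocGenerics::start(m))
}

#' miRanda-style complementarity score
#'
#' Local alignment of the miRNA against the reversed site, scoring
#' complementarity per column: Watson-Crick pair +5, G:U wobble +2,
#' mismatch -3; gap open -9, gap extend -4 (a length-L gap costs
#' 9 + 4(L-1)); columns at miRNA positions 2-8 carry double weight.
#' The best local score (never below 0) is returned. A perfect 22-nt
#' complement scores 7*5*2 + 15*5 = 145.
#'
#' @param mirna miRNA sequence.
#' @param site candidate target site sequence (given 5'->3' on the mRNA).
#' @param match,wobble,mismatch,gap_open,gap_extend scoring parameters.
#' @param seed_weight weight multiplier for miRNA positions 2-8 (default 2).
#' @return numeric score, `>= 0`.
#' @export
complementarity_score <- function(mirna, site, match = 5, wobble = 2,
                                  mismatch = -3, gap_open = -9,
                                  gap_extend = -4, seed_weight = 2) {
  mirna <- normalize_dna(mirna); site <- normalize_dna(site)
  if (nchar(site) == 0L || nchar(mirna) == 0L) return(0)
  rev_site <- paste(rev(strsplit(site, "", fixed = TRUE)[[1]]), collapse = "")
  align_score_cpp(mirna, rev_site, match, wobble, mismatch,
                  gap_open, gap_extend, 2L, 8L, seed_weight)
}

#' Predict miRNA target sites in 3'UTR sequences
#'
#' The three filters are applied in order: (1) perfect seed match (miRNA
#' positions 2-8, Watson-Crick), (2) miRNA/site duplex minimum free energy
#' below `max_energy` (strict <, default -20 kcal/mol on the package's
#' stacking-energy scale), (3) complementarity score above `min_score`
#' (strict >, default 140). All candidate sites are emitted with per-rule
#' diagnostics; the gene table lists genes with at least one passing site.
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param utrs named character vector of 3'UTR sequences; names may follow
#'   the `gene|transcript` convention, in which case the gene part is used
#'   for the gene table.
#' @param max_energy duplex energy threshold (default -20).
#' @param min_score alignment score threshold (default 140).
#' @param site_flank extra UTR bases included 5' of the site to allow 3'
#'   bulges in the miRNA/site duplex (default 4).
#' @param ... scoring parameters forwarded to [complementarity_score()].
#' @return list with `sites` (data.frame: `mirna`, `gene`, `transcript`,
#'   `site_start`, `site_end` (1-based, inclusive), `seed_match`,
#'   `duplex_energy`, `score`, `passed`) and `genes` (data.frame: `gene`,
#'   `n_sites`, `mirnas`).
#' @export
predict_targets <- function(mirnas, utrs, max_energy = -20, min_score = 140,
                            site_flank = 4L, ...) {
  mirnas <- setNames(normalize_dna(mirnas),
                     names(mirnas) %||% sprintf("mir%d", seq_along(mirnas)))
  utrs <- setNames(normalize_dna(utrs),
                   names(utrs) %||% sprintf("utr%d", seq_along(utrs)))
  rows <- list()
  for (mi in seq_along(mirnas)) {
    mir <- mirnas[mi]
    L <- nchar(mir)
    for (ui in seq_along(utrs)) {
      utr <- utrs[ui]
      gene <- sub("\\|.*$", "", names(utrs)[ui])
      tx <- if (grepl("|", names(utrs)[ui], fixed = TRUE))
        sub("^.*\\|", "", names(utrs)[ui]) else names(utrs)[ui]
      for (p in find_seed_matches(mir, utr)) {
        # seed complement occupies utr[p..p+6] (pairs miRNA 8..2);
        # miRNA position L pairs ~ utr[p - (L - 8)], position 1 pairs utr[p + 7]
        site_start <- max(1L, p - (L - 8L) - site_flank)
        site_end <- min(nchar(utr), p + 7L)
        site <- substr(utr, site_start, site_end)
        e <- duplex_free_energy(mir, site)
        sc <- complementarity_score(mir, site, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = names(mirnas)[mi], gene = gene, transcript = tx,
          site_start = site_start, site_end = site_end,
          seed_match = TRUE, duplex_energy = e, score = sc,
          passed = e < max_energy && sc > min_score,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(0), gene = character(0),
               transcript = character(0), site_start = integer(0),
               site_end = integer(0), seed_match = logical(0),
               duplex_energy = numeric(0), score = numeric(0),
               passed = logical(0), stringsAsFactors = FALSE)
  passing <- sites[sites$passed, , drop = FALSE]
  genes <- if (nrow(passing)) {
    agg <- split(passing, passing$gene)
    do.call(rbind, lapply(names(agg), function(g) {
      data.frame(gene = g, n_sites = nrow(agg[[g]]),
                 mirnas = paste(sort(unique(agg[[g]]$mirna)), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene = character(0), n_sites = integer(0), mirnas = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(sites) <- NULL
  list(sites = sites, genes = genes)
}
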
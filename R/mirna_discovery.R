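#' Excise candidate precursor windows around a mapped tag
#'
#' For each genomic hit, two windows are excised on the hit strand:
#' `[start - flank, end + 20]` and `[start - 20, end + flank]`, clipped to the
#' chromosome. The two asymmetric windows cover the cases where the mature
#' arm sits on the 3' or the 5' side of the hairpin.
#'
#' @param tag tag sequence (used only for its length bookkeeping).
#' @param hits data.frame of hits from [map_tag()].
#' @param genome named character vector of chromosome sequences.
#' @param flank flank size in nt (default 100).
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `sequence`
#'   (strand-oriented), `tag_offset` (1-based position of the tag within the
#'   window sequence).
#' @export
excise_precursor_windows <- function(tag, hits, genome, flank = 100L) {
  .stop_if(nrow(hits) == 0L, "tag has no genomic hits")
  genome <- vapply(genome, normalize_dna, character(1))
  out <- list()
  for (i in seq_len(nrow(hits))) {
    chrom <- hits$chrom[i]
    clen <- nchar(genome[[chrom]])
    s <- hits$start[i]; e <- hits$end[i]; strand <- hits$strand[i]
    for (win in list(c(s - flank, e + 20L), c(s - 20L, e + flank))) {
      ws <- max(1L, win[1]); we <- min(clen, win[2])
      seqw <- substr(genome[[chrom]], ws, we)
      if (strand == "-") {
        seqw <- revcomp(seqw)
        off <- we - e + 1L
      } else {
        off <- s - ws + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = ws, end = we, strand = strand,
        sequence = seqw, tag_offset = off, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res[!duplicated(res[, c("chrom", "start", "end", "strand")]), , drop = FALSE]
}

# longest unpaired run strictly inside the paired span of positions `span`
# (indices into the partner table)
.max_interior_bulge <- function(partner, span) {
  paired <- span[!is.na(partner[span])]
  if (length(paired) < 2L) return(Inf)
  lo <- min(paired); hi <- max(paired)
  run <- 0L; best <- 0L
  for (p in seq(lo, hi)) {
    if (is.na(partner[p])) {
      run <- run + 1L
      if (run > best) best <- run
    } else {
      run <- 0L
    }
  }
  best
}

#' Evaluate a precursor window against the hairpin rules
#'
#' Folds the window (unless a fold is supplied), locates the star arm as the
#' region pairing with the mature tag (at least `min_paired_frac` of mature
#' bases must pair), and checks the five acceptance rules: mature length in
#' \[18, 26\], precursor fold energy at most -18 kcal/mol, mature/star spacing
#' at most 35 nt, maximal bulge in the mature/star duplex at most 4 nt, and
#' read count at least 45. All thresholds are inclusive on the passing side.
#'
#' @param window one row of [excise_precursor_windows()] output (or any list
#'   with `sequence` and `tag_offset`).
#' @param tag mature tag sequence.
#' @param count read count of the tag.
#' @param fold optional precomputed [fold_rna()] result for the window.
#' @param min_len,max_len mature length bounds (18, 26).
#' @param max_energy precursor energy cutoff (-18 kcal/mol).
#' @param max_spacing mature/star loop distance cutoff (35 nt).
#' @param max_bulge bulge cutoff (4 nt).
#' @param min_count read-count cutoff (45).
#' @param min_paired_frac fraction of mature bases that must pair to call a
#'   star arm (0.6).
#' @return list of class `hairpin_candidate`: precursor fields, `fold`,
#'   `mature`, `star`, `spacing`, `max_bulge`, `passed_rules` (named logical),
#'   `accepted`.
#' @export
evaluate_candidate <- function(window, tag, count, fold = NULL,
                               min_len = 18L, max_len = 26L,
                               max_energy = -18, max_spacing = 35L,
                               max_bulge = 4L, min_count = 45L,
                               min_paired_frac = 0.6) {
  precursor <- normalize_dna(window$sequence)
  tag <- normalize_dna(tag)
  off <- window$tag_offset
  L <- nchar(tag)
  # hits may carry one substitution (the mapping policy), so the window copy
  # of the mature arm may differ from the tag at one position
  arm <- substr(precursor, off, off + L - 1L)
  .stop_if(nchar(arm) != L, "mature tag not found in window at tag_offset")
  mm <- sum(strsplit(arm, "")[[1]] != strsplit(tag, "")[[1]])
  .stop_if(mm > 1L, "mature tag not found in window at tag_offset")
  if (is.null(fold)) fold <- fold_rna(precursor)
  partner <- .pair_table(fold$structure)
  mature_span <- off:(off + L - 1L)
  partners <- partner[mature_span]
  paired_frac <- mean(!is.na(partners))
  star_found <- paired_frac >= min_paired_frac
  star <- NULL; spacing <- NA_integer_; bulge <- NA_integer_
  if (star_found) {
    star_lo <- min(partners, na.rm = TRUE)
    star_hi <- max(partners, na.rm = TRUE)
    star <- substr(precursor, star_lo, star_hi)
    spacing <- if (star_lo > max(mature_span)) {
      star_lo - max(mature_span) - 1L
    } else {
      min(mature_span) - star_hi - 1L
    }
    bulge <- max(.max_interior_bulge(partner, mature_span),
                 .max_interior_bulge(partner, star_lo:star_hi))
  }
  rules <- c(
    mature_length = L >= min_len && L <= max_len,
    energy = fold$energy <= max_energy,
    spacing = star_found && !is.na(spacing) && spacing >= 0L && spacing <= max_spacing,
    bulge = star_found && is.finite(bulge) && bulge <= max_bulge,
    count = count >= min_count
  )
  structure(
    list(
      chrom = window$chrom, start = window$start, end = window$end,
      strand = window$strand, precursor = precursor, fold = fold,
      mature = tag, count = count, star = star, spacing = spacing,
      max_bulge = bulge, passed_rules = rules, accepted = all(rules)
    ),
    class = "hairpin_candidate"
  )
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat(sprintf("hairpin candidate %s:%d-%d(%s) energy=%.1f kcal/mol %s\n",
              x$chrom %||% "?", x$start %||% NA, x$end %||% NA,
              x$strand %||% "?", x$fold$energy,
              if (x$accepted) "ACCEPTED" else "rejected"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict novel miRNAs from unannotated tags
#'
#' For every unannotated tag with at least `min_count` reads, precursor
#' windows are excised around each genomic hit, folded, and evaluated against
#' the five hairpin rules (see [evaluate_candidate()]). Candidates sharing a
#' precursor locus are deduplicated keeping the highest mature count. A
#' 5'/3' end-heterogeneity table reports, per accepted candidate, read counts
#' of shifted mature variants found in the tag set.
#'
#' @param tags data.frame of unannotated tags (`sequence`, `count`).
#' @param index a [genome_index()].
#' @param genome named character vector of chromosome sequences (same as the
#'   index was built from).
#' @param min_count read-count cutoff (default 45, inclusive).
#' @param flank excision flank (default 100).
#' @param ... further thresholds passed to [evaluate_candidate()].
#' @return list with `accepted` (list of `hairpin_candidate`), `table`
#'   (data.frame: locus, energy, spacing, bulge, counts, rule flags, accepted)
#'   over all evaluated candidates, and `heterogeneity` (data.frame of
#'   5'/3'-shifted variant read counts per accepted candidate).
#' @export
predict_novel_mirnas <- function(tags, index, genome, min_count = 45L,
                                 flank = 100L, ...) {
  genome <- vapply(genome, normalize_dna, character(1))
  eligible <- tags[tags$count >= min_count & !grepl("N", tags$sequence), , drop = FALSE]
  cands <- list()
  rows <- list()
  if (nrow(eligible) > 0L) {
    for (i in seq_len(nrow(eligible))) {
      s <- normalize_dna(eligible$sequence[i])
      hits <- map_tag(s, index)
      if (nrow(hits) == 0L) next
      wins <- excise_precursor_windows(s, hits, genome, flank = flank)
      for (w in seq_len(nrow(wins))) {
        cand <- evaluate_candidate(wins[w, ], s, eligible$count[i],
                                   min_count = min_count, ...)
        cands[[length(cands) + 1L]] <- cand
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cand$chrom, start = cand$start, end = cand$end,
          strand = cand$strand, mature = s, count = eligible$count[i],
          energy = cand$fold$energy, spacing = cand$spacing,
          max_bulge = ifelse(is.finite(cand$max_bulge), cand$max_bulge, NA),
          rule_length = cand$passed_rules[["mature_length"]],
          rule_energy = cand$passed_rules[["energy"]],
          rule_spacing = cand$passed_rules[["spacing"]],
          rule_bulge = cand$passed_rules[["bulge"]],
          rule_count = cand$passed_rules[["count"]],
          accepted = cand$accepted, stringsAsFactors = FALSE
        )
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), mature = character(0), count = integer(0),
               energy = numeric(0), spacing = integer(0), max_bulge = numeric(0),
               rule_length = logical(0), rule_energy = logical(0),
               rule_spacing = logical(0), rule_bulge = logical(0),
               rule_count = logical(0), accepted = logical(0),
               stringsAsFactors = FALSE)
  # deduplicate accepted candidates sharing a locus: keep highest mature count
  # (a hairpin's two arms are mutual reverse complements, so the same genomic
  # locus surfaces on both strands: dedup is strand-blind)
  acc <- cands[vapply(cands, function(x) x$accepted, logical(1))]
  if (length(acc) > 1L) {
    # greedy keep by descending mature count
    ord <- order(-vapply(acc, `[[`, numeric(1), "count"))
    acc <- acc[ord]
    keep <- logical(length(acc))
    for (i in seq_along(acc)) {
      dup <- FALSE
      for (j in which(keep)) {
        if (acc[[i]]$chrom == acc[[j]]$chrom &&
            acc[[i]]$start <= acc[[j]]$end && acc[[j]]$start <= acc[[i]]$end) {
          dup <- TRUE
          break
        }
      }
      keep[i] <- !dup
    }
    acc <- acc[keep]
  }
  het <- .heterogeneity_table(acc, tags, genome)
  list(accepted = acc, table = tab, heterogeneity = het)
}

# read counts of 5'- vs 3'-shifted mature variants per accepted candidate
.heterogeneity_table <- function(accepted, tags, genome) {
  rows <- list()
  for (cand in accepted) {
    prec <- cand$precursor
    m <- cand$mature
    moff <- regexpr(m, prec, fixed = TRUE)[1]
    c5 <- 0; c3 <- 0; cexact <- 0
    for (i in seq_len(nrow(tags))) {
      s <- normalize_dna(tags$sequence[i])
      off <- regexpr(s, prec, fixed = TRUE)[1]
      if (off < 0) next
      send <- off + nchar(s) - 1L
      mend <- moff + nchar(m) - 1L
      if (off == moff && send == mend) {
        cexact <- cexact + tags$count[i]
      } else if (abs(off - moff) <= 4L && abs(send - mend) <= 4L) {
        if (off != moff) c5 <- c5 + tags$count[i]
        if (send != mend) c3 <- c3 + tags$count[i]
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = cand$chrom, start = cand$start, strand = cand$strand,
      mature = m, exact_reads = cexact, shifted5_reads = c5,
      shifted3_reads = c3, stringsAsFactors = FALSE
    )
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), strand = character(0),
               mature = character(0), exact_reads = numeric(0),
               shifted5_reads = numeric(0), shifted3_reads = numeric(0),
               stringsAsFactors = FALSE)
}
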
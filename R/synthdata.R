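#' Configuration for the synthetic small-RNA study
#'
#' Defaults define the standard desk-scale study conditions: a three-
#' chromosome 90-kb genome; six known miRNA hairpins with a 22-nt mature
#' length and log-spread abundances; four novel rule-satisfying hairpins and
#' four pairing-depleted decoy loci, all with read stacks of at least 45;
#' twenty-five piRNAs (26-27 nt mode, lengths 24-31) over five loci whose ten
#' most abundant carry exactly 61% of piRNA reads; the usual non-coding
#' classes, repeats and retrotransposons; thirty 3'UTRs of which eight carry
#' perfect-complement miRNA target sites; and GO/pathway vocabularies with
#' one planted enriched term each. piRNA sequences are derived antisense from
#' the repeat classes in proportions 17:2:4:2 (LINE1, LTR, repeat, mRNA),
#' i.e. 76% retrotransposon-derived, mirroring the reported target-class
#' breakdown.
#'
#' @param ... overrides for any default field.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(...) {
  cfg <- list(
    chrom_lengths = c(chr1 = 40000L, chr2 = 30000L, chr3 = 20000L),
    # miRNA hairpins (mature 22 nt, perfect stem, 12-nt loop)
    n_known_mirnas = 6L,
    known_mirna_counts = c(1200L, 800L, 500L, 300L, 150L, 80L),
    n_novel_hairpins = 4L,
    novel_counts = c(150L, 110L, 90L, 70L),
    n_decoy_hairpins = 4L,
    decoy_counts = c(140L, 105L, 85L, 68L),
    mature_length = 22L,
    loop_length = 12L,
    # piRNAs: 5 loci x 5; the 10 most abundant carry 915/1500 = 61% of reads
    n_pirna_loci = 5L,
    pirnas_per_locus = 5L,
    pirna_counts = c(200L, 150L, 120L, 100L, 80L, 70L, 60L, 50L, 45L, 40L,
                     rep(39L, 15L)),
    pirna_target_classes = c(rep("retrotransposon:LINE1", 17L),
                             rep("retrotransposon:LTR", 2L),
                             rep("repeat", 4L), rep("mRNA", 2L)),
    pirna_locus_length = 160L,
    # other small-RNA classes: (n features, feature length, per-feature counts)
    ncrna = list(
      rRNA = list(n = 3L, len = 150L, counts = c(180L, 120L, 100L)),
      tRNA = list(n = 3L, len = 72L, counts = c(60L, 50L, 40L)),
      snRNA = list(n = 2L, len = 110L, counts = c(60L, 40L)),
      snoRNA = list(n = 2L, len = 90L, counts = c(45L, 35L)),
      scRNA = list(n = 1L, len = 130L, counts = 40L),
      srpRNA = list(n = 1L, len = 140L, counts = 30L)
    ),
    n_repeat = 4L, repeat_length = 200L, repeat_counts = c(200L, 150L, 120L, 80L),
    n_line1 = 3L, line1_length = 250L, line1_counts = c(120L, 90L, 60L),
    n_ltr = 2L, ltr_length = 220L, ltr_counts = c(70L, 50L),
    # mRNA 3'UTRs and target planting
    n_utrs = 30L, utr_length = 400L,
    n_target_utrs = 8L, n_decoy_site_utrs = 4L,
    n_mrna_tags = 6L, mrna_tag_counts = rep(30L, 6L),
    # annotation vocabularies
    n_genes = 400L, n_go_terms = 25L, n_pathways = 12L,
    # editing
    n_edited_mirnas = 2L, edit_fraction = 0.15, edit_position = 10L,
    # read model
    read_length = 36L,
    adapter5 = default_adapters()$adapter5,
    adapter3 = default_adapters()$adapter3,
    trim5_prob = 0.08, trim3_prob = 0.18, pirna_trim_prob = 0.15,
    error_rate = 0.002, contamination = 0.03, frac_low_quality = 0.02,
    # ping-pong simulation
    pingpong_pairs_per_locus = 150L,
    bias_1u = 0.95, bias_10a = 0.95
  )
  over <- list(...)
  .stop_if(length(over) && is.null(names(over)), "overrides must be named")
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = c("synth_config", "list"))
}

# evaluate expr with a temporary RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# adapter-derived motifs no read-generating sequence may contain (on either
# strand): a >=6-nt adapter hit inside an insert would corrupt trimming
.forbidden_motifs <- function(adapter5, adapter3, min_overlap = 6L) {
  m <- c(substr(adapter3, 1L, min_overlap),
         substr(adapter5, nchar(adapter5) - min_overlap + 1L, nchar(adapter5)))
  unique(c(m, revcomp(m)))
}

.has_motif <- function(s, motifs) {
  any(vapply(motifs, function(m) grepl(m, s, fixed = TRUE), logical(1)))
}

.random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# random sequence free of adapter motifs on both strands
.clean_dna <- function(len, motifs, alphabet = c("A", "C", "G", "T"),
                       max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    s <- .random_dna(len, alphabet)
    if (!.has_motif(s, motifs)) return(s)
  }
  stop("could not generate an adapter-motif-free sequence", call. = FALSE)
}

# non-overlapping placement of `len`-nt features on the genome; returns
# (chrom, start); errors when capacity is exhausted
.place_feature <- function(len, chrom_lengths, occupied, gap = 10L,
                           max_tries = 500L) {
  for (i in seq_len(max_tries)) {
    chrom <- sample(names(chrom_lengths), 1L,
                    prob = as.numeric(chrom_lengths) / sum(chrom_lengths))
    clen <- chrom_lengths[[chrom]]
    if (clen < len + 2L) next
    start <- sample.int(clen - len + 1L, 1L)
    end <- start + len - 1L
    occ <- occupied[[chrom]]
    clash <- FALSE
    if (!is.null(occ) && nrow(occ) > 0L) {
      clash <- any(start <= occ$end + gap & occ$start - gap <= end)
    }
    if (!clash) return(list(chrom = chrom, start = start, end = end))
  }
  stop("cannot place feature of length ", len,
       ": genome capacity exhausted (reduce feature counts or enlarge chromosomes)",
       call. = FALSE)
}

#' Generate the synthetic genome, reference catalogs and truth table
#'
#' Deterministic for a fixed seed and config. The genome carries
#' non-overlapping planted features (miRNA hairpins, novel hairpins, decoy
#' loci, piRNA loci, non-coding RNA classes, repeats, retrotransposons,
#' 3'UTRs); reference catalog sequences are genome substrings at their
#' feature coordinates (reverse-complemented for minus-strand features); and
#' the truth table records every planted entity with its expected read count.
#' All read-generating sequences avoid adapter-derived 6-mers on both strands
#' so adapter trimming is exact on noise-free data.
#'
#' @param seed integer RNG seed.
#' @param config a [synth_config()].
#' @return list with `genome` (named character vector), `features`
#'   (data.frame: chrom, start, end, strand, class, id), `references` (named
#'   list of catalogs for the annotation cascade: miRNA, piRNA, rRNA, tRNA,
#'   snRNA, snoRNA, scRNA, srpRNA, `repeat`, mRNA; plus `repeat_classes`),
#'   `go_map` and `pathway_map` (data.frames gene/term), `truth` (truth
#'   table), and `config`.
#' @export
generate_references <- function(seed, config = synth_config()) {
  .with_seed(seed, .generate_references_impl(config))
}

.generate_references_impl <- function(cfg) {
  motifs <- .forbidden_motifs(cfg$adapter5, cfg$adapter3)
  chrom_lengths <- cfg$chrom_lengths
  occupied <- setNames(vector("list", length(chrom_lengths)), names(chrom_lengths))
  feats <- list()
  segments <- list() # per chrom: list of (start, seq) to splice in

  add_feature <- function(seq, class, id, strand) {
    loc <- .place_feature(nchar(seq), chrom_lengths, occupied)
    occupied[[loc$chrom]] <<- rbind(
      occupied[[loc$chrom]],
      data.frame(start = loc$start, end = loc$end)
    )
    gseq <- if (strand == "+") seq else revcomp(seq)
    segments[[length(segments) + 1L]] <<- list(chrom = loc$chrom,
                                               start = loc$start, seq = gseq)
    feats[[length(feats) + 1L]] <<- data.frame(
      chrom = loc$chrom, start = loc$start, end = loc$end, strand = strand,
      class = class, id = id, stringsAsFactors = FALSE
    )
    loc
  }

  # --- hairpins ---------------------------------------------------------
  make_hairpin <- function(id, role, count) {
    repeat {
      mature <- .clean_dna(cfg$mature_length, motifs)
      loop <- .clean_dna(cfg$loop_length, motifs)
      star <- revcomp(mature)
      arm5 <- sample(c(TRUE, FALSE), 1L)
      prec <- if (arm5) paste0(mature, loop, star) else paste0(star, loop, mature)
      if (!.has_motif(prec, motifs)) break
    }
    loc <- add_feature(prec, "mirna_hairpin", id, "+")
    moff <- if (arm5) 0L else cfg$mature_length + cfg$loop_length
    data.frame(
      id = id, role = role, mature = mature, star = star, precursor = prec,
      chrom = loc$chrom, start = loc$start + moff,
      end = loc$start + moff + cfg$mature_length - 1L, strand = "+",
      expected_count = count, stringsAsFactors = FALSE
    )
  }
  mirnas <- list()
  for (i in seq_len(cfg$n_known_mirnas)) {
    mirnas[[length(mirnas) + 1L]] <-
      make_hairpin(sprintf("mir-syn-%d", i), "known", cfg$known_mirna_counts[i])
  }
  for (i in seq_len(cfg$n_novel_hairpins)) {
    mirnas[[length(mirnas) + 1L]] <-
      make_hairpin(sprintf("novel-%d", i), "novel", cfg$novel_counts[i])
  }
  # decoys: pairing-depleted A/C-only loci (fold energy 0 > -18); the 22-nt
  # decoy tag sits mid-feature so both excision windows stay inside it
  for (i in seq_len(cfg$n_decoy_hairpins)) {
    id <- sprintf("decoy-%d", i)
    flank <- 120L
    left <- .clean_dna(flank, motifs, alphabet = c("A", "C"))
    tag <- .clean_dna(cfg$mature_length, motifs, alphabet = c("A", "C"))
    right <- .clean_dna(flank, motifs, alphabet = c("A", "C"))
    feat <- paste0(left, tag, right)
    loc <- add_feature(feat, "mirna_hairpin", id, "+")
    mirnas[[length(mirnas) + 1L]] <- data.frame(
      id = id, role = "decoy", mature = tag, star = NA_character_,
      precursor = feat, chrom = loc$chrom, start = loc$start + flank,
      end = loc$start + flank + cfg$mature_length - 1L, strand = "+",
      expected_count = cfg$decoy_counts[i], stringsAsFactors = FALSE
    )
  }
  planted_mirnas <- do.call(rbind, mirnas)

  # --- repeats / retrotransposons (needed before piRNAs) ----------------
  rep_seqs <- character(0); rep_classes <- character(0)
  add_repeats <- function(n, len, class, prefix) {
    for (i in seq_len(n)) {
      s <- .clean_dna(len, motifs)
      id <- sprintf("%s%d", prefix, i)
      add_feature(s, if (class == "repeat") "repeat" else
        paste0("retrotransposon:", sub("retrotransposon:", "", class)), id,
        sample(c("+", "-"), 1L))
      rep_seqs[[id]] <<- s
      rep_classes[[id]] <<- class
    }
  }
  add_repeats(cfg$n_repeat, cfg$repeat_length, "repeat", "rep")
  add_repeats(cfg$n_line1, cfg$line1_length, "retrotransposon:LINE1", "L1_")
  add_repeats(cfg$n_ltr, cfg$ltr_length, "retrotransposon:LTR", "LTR")

  # --- 3'UTRs (needed before piRNAs for mRNA-derived piRNA targets) -----
  utr_seqs <- character(0)
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  for (i in seq_len(cfg$n_utrs)) {
    nm <- sprintf("%s|TX%04d", genes[i], i)
    utr_seqs[[nm]] <- .clean_dna(cfg$utr_length, motifs)
  }

  # --- piRNA loci -------------------------------------------------------
  n_pirnas <- cfg$n_pirna_loci * cfg$pirnas_per_locus
  .stop_if(length(cfg$pirna_counts) != n_pirnas,
           "pirna_counts must have n_pirna_loci * pirnas_per_locus entries")
  classes <- rep(cfg$pirna_target_classes, length.out = n_pirnas)
  pirna_rows <- list()
  n_t <- min(cfg$n_target_utrs, cfg$n_utrs)
  n_d <- min(cfg$n_decoy_site_utrs, max(0L, cfg$n_utrs - n_t))
  used_segments <- list() # per source id: taken intervals, so catalog entries
                          # never become near-duplicates that cross-match tags
  pirna_seq_of_class <- function(len, class) {
    pool <- if (class %in% c("retrotransposon:LINE1", "retrotransposon:LTR", "repeat")) {
      rep_seqs[rep_classes == class]
    } else if (class == "mRNA" && length(utr_seqs) > n_t + n_d) {
      # only UTRs that never receive target-site edits stay verbatim
      utr_seqs[(n_t + n_d + 1L):length(utr_seqs)]
    } else {
      character(0)
    }
    if (length(pool) == 0L) {
      # 'other': random, assigned to no target class
      return(.clean_dna(len, motifs))
    }
    for (try in 1:200) {
      pick <- sample.int(length(pool), 1L)
      src <- pool[[pick]]
      key <- paste0(class, "#", pick)
      start <- sample.int(nchar(src) - len + 1L, 1L)
      end <- start + len - 1L
      taken <- used_segments[[key]]
      if (!is.null(taken) &&
          any(start <= taken$end + 5L & taken$start - 5L <= end)) next
      used_segments[[key]] <<- rbind(taken, data.frame(start = start, end = end))
      return(revcomp(substr(src, start, end)))
    }
    .clean_dna(len, motifs)
  }
  k <- 0L
  for (li in seq_len(cfg$n_pirna_loci)) {
    pieces <- character(0)
    ids <- character(0); lens <- integer(0); pcls <- character(0)
    for (pi in seq_len(cfg$pirnas_per_locus)) {
      k <- k + 1L
      len <- if (runif(1) < 0.6) sample(26:27, 1L) else sample(24:31, 1L)
      cls <- classes[k]
      s <- pirna_seq_of_class(len, cls)
      # 1U bias on primary piRNAs (T in DNA space)
      if (runif(1) < 0.9) substr(s, 1L, 1L) <- "T"
      if (.has_motif(s, motifs)) {
        s <- .clean_dna(len, motifs)
        cls <- "other" # no longer traceable to its source class
      }
      ids <- c(ids, sprintf("piR-syn-%03d", k))
      lens <- c(lens, len)
      pcls <- c(pcls, cls)
      pieces <- c(pieces, s)
    }
    spacers <- vapply(seq_len(length(pieces) + 1L),
                      function(i) .clean_dna(6L, motifs), character(1))
    locus <- paste0(spacers[1],
                    paste0(pieces, spacers[-1], collapse = ""))
    extra <- cfg$pirna_locus_length - nchar(locus)
    if (extra > 0L) locus <- paste0(locus, .clean_dna(extra, motifs))
    strand <- sample(c("+", "-"), 1L)
    loc <- add_feature(locus, "pirna_locus", sprintf("piLocus-%d", li), strand)
    # piRNA coordinates within the locus (transcribed orientation)
    off <- nchar(spacers[1])
    for (pi in seq_along(pieces)) {
      idx <- (li - 1L) * cfg$pirnas_per_locus + pi
      if (strand == "+") {
        ps <- loc$start + off
        pe <- ps + lens[pi] - 1L
      } else {
        pe <- loc$end - off
        ps <- pe - lens[pi] + 1L
      }
      pirna_rows[[idx]] <- data.frame(
        id = ids[pi], sequence = pieces[pi], target_class = pcls[pi],
        locus = sprintf("piLocus-%d", li), chrom = loc$chrom,
        start = ps, end = pe, strand = strand,
        expected_count = cfg$pirna_counts[idx],
        is_pingpong_responder = FALSE, stringsAsFactors = FALSE
      )
      off <- off + lens[pi] + nchar(spacers[pi + 1L])
    }
  }
  planted_pirnas <- if (length(pirna_rows)) do.call(rbind, pirna_rows) else
    data.frame(id = character(0), sequence = character(0),
               target_class = character(0), locus = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), expected_count = integer(0),
               is_pingpong_responder = logical(0), stringsAsFactors = FALSE)

  # --- other non-coding classes -----------------------------------------
  other_rows <- list()
  refs_nc <- list()
  for (class in names(cfg$ncrna)) {
    spec <- cfg$ncrna[[class]]
    seqs <- character(0)
    for (i in seq_len(spec$n)) {
      id <- sprintf("%s-%d", class, i)
      s <- .clean_dna(spec$len, motifs)
      loc <- add_feature(s, tolower(class), id, sample(c("+", "-"), 1L))
      seqs[[id]] <- s
      # one read-generating tag per feature: a random 20-26 nt substring
      tl <- sample(20:26, 1L)
      ts <- sample.int(spec$len - tl + 1L, 1L)
      other_rows[[length(other_rows) + 1L]] <- data.frame(
        id = paste0(id, "_tag"), class = class,
        sequence = substr(s, ts, ts + tl - 1L),
        expected_count = spec$counts[i], stringsAsFactors = FALSE
      )
    }
    refs_nc[[class]] <- seqs
  }
  # repeat-derived tags
  rep_counts <- c(cfg$repeat_counts, cfg$line1_counts, cfg$ltr_counts)
  for (i in seq_along(rep_seqs)) {
    s <- rep_seqs[[i]]
    tl <- sample(20:28, 1L)
    ts <- sample.int(nchar(s) - tl + 1L, 1L)
    other_rows[[length(other_rows) + 1L]] <- data.frame(
      id = paste0(names(rep_seqs)[i], "_tag"), class = "repeat",
      sequence = substr(s, ts, ts + tl - 1L),
      expected_count = rep_counts[i], stringsAsFactors = FALSE
    )
  }
  # --- place UTR features on the genome; plant target sites -------------
  known <- planted_mirnas[planted_mirnas$role == "known", , drop = FALSE]
  target_rows <- list()
  for (i in seq_len(cfg$n_utrs)) {
    nm <- names(utr_seqs)[i]
    s <- utr_seqs[[nm]]
    gene <- sub("\\|.*$", "", nm)
    tx <- sub("^.*\\|", "", nm)
    if (i <= n_t && nrow(known)) {
      # perfect complement of a top known miRNA
      mi <- ((i - 1L) %% min(3L, nrow(known))) + 1L
      site <- revcomp(known$mature[mi])
      pos <- sample(seq(20L, nchar(s) - nchar(site) - 20L), 1L)
      repeat {
        s2 <- paste0(substr(s, 1L, pos - 1L), site,
                     substr(s, pos + nchar(site), nchar(s)))
        if (!.has_motif(s2, motifs)) break
        s <- .clean_dna(cfg$utr_length, motifs)
      }
      s <- s2
      target_rows[[length(target_rows) + 1L]] <- data.frame(
        gene = gene, transcript = tx, mirna_id = known$id[mi],
        utr_pos = pos, decoy = FALSE, stringsAsFactors = FALSE
      )
    } else if (i <= n_t + n_d && nrow(known)) {
      # seed-only decoy: seed complement followed by a non-complementary tail
      mi <- ((i - 1L) %% min(3L, nrow(known))) + 1L
      seed_rc <- revcomp(substr(known$mature[mi], 2L, 8L))
      pos <- sample(seq(20L, nchar(s) - 7L - 20L), 1L)
      s2 <- paste0(substr(s, 1L, pos - 1L), seed_rc,
                   substr(s, pos + 7L, nchar(s)))
      if (!.has_motif(s2, motifs)) s <- s2
      target_rows[[length(target_rows) + 1L]] <- data.frame(
        gene = gene, transcript = tx, mirna_id = known$id[mi],
        utr_pos = pos, decoy = TRUE, stringsAsFactors = FALSE
      )
    }
    utr_seqs[[nm]] <- s
    add_feature(s, "mrna_utr", nm, "+")
  }
  planted_targets <- if (length(target_rows)) do.call(rbind, target_rows) else
    data.frame(gene = character(0), transcript = character(0),
               mirna_id = character(0), utr_pos = integer(0),
               decoy = logical(0), stringsAsFactors = FALSE)

  # mRNA (UTR degradation) tags, sampled from the finalized UTR sequences
  if (cfg$n_mrna_tags > 0L && length(utr_seqs)) {
    pick <- sample(seq_along(utr_seqs), cfg$n_mrna_tags,
                   replace = cfg$n_mrna_tags > length(utr_seqs))
    for (i in seq_len(cfg$n_mrna_tags)) {
      s <- utr_seqs[[pick[i]]]
      tl <- sample(18:28, 1L)
      ts <- sample.int(nchar(s) - tl + 1L, 1L)
      other_rows[[length(other_rows) + 1L]] <- data.frame(
        id = sprintf("mrna_tag-%d", i), class = "mRNA",
        sequence = substr(s, ts, ts + tl - 1L),
        expected_count = cfg$mrna_tag_counts[i], stringsAsFactors = FALSE
      )
    }
  }
  planted_other <- do.call(rbind, other_rows)

  # --- assemble genome ---------------------------------------------------
  genome <- vapply(names(chrom_lengths), function(ch) {
    .random_dna(chrom_lengths[[ch]])
  }, character(1))
  for (seg in segments) {
    s <- genome[[seg$chrom]]
    genome[[seg$chrom]] <- paste0(
      substr(s, 1L, seg$start - 1L), seg$seq,
      substr(s, seg$start + nchar(seg$seq), nchar(s))
    )
  }
  features <- do.call(rbind, feats)

  # --- editing truth -----------------------------------------------------
  edit_rows <- list()
  kn <- which(planted_mirnas$role == "known")
  n_ed <- min(cfg$n_edited_mirnas, length(kn))
  if (n_ed > 0L) {
    for (i in seq_len(n_ed)) {
      row <- kn[i]
      pos <- cfg$edit_position
      ref <- substr(planted_mirnas$mature[row], pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      edit_rows[[i]] <- data.frame(
        mirna_id = planted_mirnas$id[row], position = pos, alt_base = alt,
        fraction = cfg$edit_fraction, stringsAsFactors = FALSE
      )
    }
  }
  planted_edits <- if (length(edit_rows)) do.call(rbind, edit_rows) else
    data.frame(mirna_id = character(0), position = integer(0),
               alt_base = character(0), fraction = numeric(0),
               stringsAsFactors = FALSE)

  # --- GO / pathway maps -------------------------------------------------
  go_terms <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  pathways <- sprintf("PW:%05d", seq_len(cfg$n_pathways))
  target_genes <- unique(planted_targets$gene[!planted_targets$decoy])
  go_map <- .build_term_map(genes, go_terms, target_genes,
                            enriched_term = "GO:9999001",
                            n_background_with_term = 8L, terms_per_gene = 1:3)
  pathway_map <- .build_term_map(genes, pathways, target_genes,
                                 enriched_term = "PW:99901",
                                 n_background_with_term = 10L,
                                 terms_per_gene = 1:2)

  refs <- c(
    list(
      miRNA = setNames(known$mature, known$id),
      piRNA = setNames(planted_pirnas$sequence, planted_pirnas$id)
    ),
    refs_nc,
    list(
      `repeat` = rep_seqs,
      mRNA = utr_seqs,
      repeat_classes = rep_classes
    )
  )

  truth <- list(
    planted_mirnas = planted_mirnas,
    planted_pirnas = planted_pirnas,
    planted_edits = planted_edits,
    planted_other = planted_other,
    planted_targets = planted_targets,
    enriched_go_term = "GO:9999001",
    enriched_pathway = "PW:99901"
  )
  list(genome = genome, features = features, references = refs,
       go_map = go_map, pathway_map = pathway_map, truth = truth,
       config = cfg)
}

# gene -> term map with one planted enriched term among the target genes
.build_term_map <- function(genes, terms, target_genes, enriched_term,
                            n_background_with_term, terms_per_gene) {
  rows <- lapply(genes, function(g) {
    k <- sample(terms_per_gene, 1L)
    data.frame(gene = g, term = sample(terms, k), stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  extra <- list()
  if (length(target_genes)) {
    carriers <- target_genes[seq_len(max(1L, length(target_genes) - 1L))]
    extra[[1]] <- data.frame(gene = carriers, term = enriched_term,
                             stringsAsFactors = FALSE)
  }
  bg <- sample(setdiff(genes, target_genes), n_background_with_term)
  extra[[length(extra) + 1L]] <- data.frame(gene = bg, term = enriched_term,
                                            stringsAsFactors = FALSE)
  map <- rbind(map, do.call(rbind, extra))
  map[!duplicated(map), , drop = FALSE]
}
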
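# one insert drawn for a truth entry (variant trimming + editing + errors)
.mutate_bases <- function(s, positions, alphabet = c("A", "C", "G", "T")) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in positions) v[p] <- sample(setdiff(alphabet, v[p]), 1L)
  paste(v, collapse = "")
}

.apply_errors <- function(s, error_rate) {
  if (error_rate <= 0) return(s)
  hits <- which(runif(nchar(s)) < error_rate)
  if (length(hits) == 0L) return(s)
  .mutate_bases(s, hits)
}

# assemble a fixed-length read from an insert: insert + 3' adapter, truncated
.assemble_read <- function(insert, adapter3, read_length) {
  s <- paste0(insert, adapter3)
  while (nchar(s) < read_length) s <- paste0(s, adapter3)
  substr(s, 1L, read_length)
}

#' Simulate a raw small-RNA library from a truth table
#'
#' Each truth entry (planted miRNAs — known, novel and decoy —, piRNAs and
#' the other planted classes) yields reads consisting of the insert followed
#' by the 3' adapter, truncated to the fixed read length, with offset-64
#' qualities. miRNA inserts show 5'/3' end heterogeneity (1-nt trims, more
#' frequent at the 3' end); piRNA inserts longer than
#' `read_length - adapter overlap` are trimmed so the adapter stays
#' detectable; planted editing events substitute the recorded base in the
#' configured fraction of that miRNA's reads. Contaminant reads (adapter
#' dimers and N-containing reads) and low-quality reads (one base with
#' Q < 10) are appended as extra reads so that, at `error_rate = 0`, clean
#' read counts equal the planted expected counts exactly.
#'
#' @param truth truth table from [generate_references()] (`$truth`).
#' @param n_reads total reads for a multinomial draw over truth entries with
#'   probabilities proportional to expected counts, or `NULL` (default) to
#'   emit exactly `expected_count` reads per entry.
#' @param error_rate per-base substitution probability, in `[0, 0.1)`.
#' @param contamination fraction of extra contaminant reads.
#' @param frac_low_quality fraction of extra low-quality reads.
#' @param seed RNG seed.
#' @param config a [synth_config()] (read length, adapters, trim
#'   probabilities).
#' @return data.frame of raw reads: `id`, `sequence`, `quality`, plus a
#'   `truth_id` column (`NA` for contaminant/low-quality reads).
#' @export
simulate_library <- function(truth, n_reads = NULL, error_rate = 0,
                             contamination = 0, frac_low_quality = 0,
                             seed = 1L, config = synth_config()) {
  .stop_if(error_rate < 0 || error_rate >= 0.1, "error_rate must be in [0, 0.1)")
  .stop_if(!is.null(n_reads) && n_reads <= 0, "n_reads must be positive")
  .with_seed(seed, .simulate_library_impl(truth, n_reads, error_rate,
                                          contamination, frac_low_quality,
                                          config))
}

.simulate_library_impl <- function(truth, n_reads, error_rate, contamination,
                                   frac_low_quality, cfg) {
  mi <- truth$planted_mirnas
  pi_ <- truth$planted_pirnas
  ot <- truth$planted_other
  entries <- rbind(
    data.frame(truth_id = mi$id, sequence = mi$mature, kind = "mirna",
               expected_count = mi$expected_count, stringsAsFactors = FALSE),
    data.frame(truth_id = pi_$id, sequence = pi_$sequence, kind = "pirna",
               expected_count = pi_$expected_count, stringsAsFactors = FALSE),
    if (!is.null(ot) && nrow(ot)) data.frame(
      truth_id = ot$id, sequence = ot$sequence, kind = "other",
      expected_count = ot$expected_count, stringsAsFactors = FALSE)
  )
  counts <- if (is.null(n_reads)) {
    entries$expected_count
  } else {
    as.integer(rmultinom(1L, n_reads,
                         entries$expected_count / sum(entries$expected_count)))
  }
  edits <- truth$planted_edits
  # longest insert whose 3' adapter overlap stays detectable (>= 6 nt)
  max_insert <- cfg$read_length - 6L
  seqs <- character(0)
  truth_ids <- character(0)
  for (i in seq_len(nrow(entries))) {
    n_i <- counts[i]
    if (n_i == 0L) next
    base <- entries$sequence[i]
    kind <- entries$kind[i]
    ins <- rep(base, n_i)
    if (kind == "mirna") {
      ed <- edits[edits$mirna_id == entries$truth_id[i], , drop = FALSE]
      if (nrow(ed)) {
        hit <- runif(n_i) < ed$fraction[1]
        ins[hit] <- vapply(ins[hit], function(s) {
          v <- strsplit(s, "", fixed = TRUE)[[1]]
          v[ed$position[1]] <- ed$alt_base[1]
          paste(v, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      t5 <- runif(n_i) < cfg$trim5_prob
      t3 <- runif(n_i) < cfg$trim3_prob
      ins <- substr(ins, 1L + t5, nchar(ins) - t3)
    } else if (kind == "pirna") {
      t5 <- runif(n_i) < cfg$pirna_trim_prob
      ins <- substr(ins, 1L + t5, nchar(ins))
      over <- nchar(ins) > max_insert
      ins[over] <- substr(ins[over], 1L, max_insert)
    }
    if (error_rate > 0) ins <- vapply(ins, .apply_errors, character(1),
                                      error_rate = error_rate, USE.NAMES = FALSE)
    seqs <- c(seqs, ins)
    truth_ids <- c(truth_ids, rep(entries$truth_id[i], n_i))
  }
  reads <- vapply(seqs, .assemble_read, character(1),
                  adapter3 = cfg$adapter3, read_length = cfg$read_length,
                  USE.NAMES = FALSE)
  quals <- rep(strrep("h", cfg$read_length), length(reads)) # Q = 40
  n_main <- length(reads)
  # contaminant reads: adapter dimers and N-containing inserts
  n_cont <- round(contamination * n_main)
  if (n_cont > 0L) {
    half <- n_cont %/% 2L
    dimers <- rep(substr(strrep(cfg$adapter3, 3L), 1L, cfg$read_length),
                  half)
    n_n <- n_cont - half
    nreads <- vapply(sample(seqs, n_n, replace = TRUE), function(s) {
      p <- sample.int(nchar(s), 1L)
      substr(s, p, p) <- "N"
      .assemble_read(s, cfg$adapter3, cfg$read_length)
    }, character(1), USE.NAMES = FALSE)
    reads <- c(reads, dimers, nreads)
    quals <- c(quals, rep(strrep("h", cfg$read_length), n_cont))
    truth_ids <- c(truth_ids, rep(NA_character_, n_cont))
  }
  # low-quality reads: one base at Q = -24 ('(' = 40 - 64)
  n_lq <- round(frac_low_quality * n_main)
  if (n_lq > 0L) {
    lq_seqs <- sample(seqs, n_lq, replace = TRUE)
    lq_reads <- vapply(lq_seqs, .assemble_read, character(1),
                       adapter3 = cfg$adapter3, read_length = cfg$read_length,
                       USE.NAMES = FALSE)
    lq_quals <- vapply(seq_len(n_lq), function(i) {
      q <- strrep("h", cfg$read_length)
      p <- sample.int(cfg$read_length, 1L)
      substr(q, p, p) <- "("
      q
    }, character(1))
    reads <- c(reads, lq_reads)
    quals <- c(quals, lq_quals)
    truth_ids <- c(truth_ids, rep(NA_character_, n_lq))
  }
  ord <- sample.int(length(reads))
  data.frame(
    id = sprintf("synread%06d", seq_along(reads)),
    sequence = reads[ord], quality = quals[ord], truth_id = truth_ids[ord],
    stringsAsFactors = FALSE
  )
}

#' Simulate ping-pong piRNA read pairs from a locus
#'
#' Generates sense/antisense read pairs whose 5' ends overlap by exactly
#' `overlap` nt, the ping-pong signature: a primary (sense) read starting at
#' locus position s is matched by a responder (antisense) read whose 5' end
#' sits at s + overlap - 1. Primary reads start with U (T in DNA space) with
#' probability `bias_1u` (anchors are drawn from T/non-T start positions in
#' the given proportion); responder reads carry A at position 10 with
#' probability `bias_10a` (forced by complementarity when the primary starts
#' with T, otherwise overridden in the read).
#'
#' @param locus locus sequence (single string, length at least 40), or a list
#'   with `sequence`, `chrom`, `start`, `strand` for genome-aware output.
#' @param n_pairs number of read pairs.
#' @param seed RNG seed.
#' @param bias_1u realized fraction of primary reads starting with T.
#' @param bias_10a realized fraction of responder reads with A at position 10.
#' @param overlap 5'-overlap length (default 10).
#' @param length_range read length range, default 26-28 nt.
#' @param config a [synth_config()] (read length, adapter).
#' @return data.frame of reads: `id`, `sequence`, `quality`, `insert`,
#'   `chrom`, `start`, `end` (1-based genomic, assuming a plus-strand locus),
#'   `strand`, `role` (`"primary"`/`"responder"`), `pair` (pair index).
#' @export
simulate_pingpong_reads <- function(locus, n_pairs, seed = 1L,
                                    bias_1u = 0.95, bias_10a = 0.95,
                                    overlap = 10L, length_range = c(26L, 28L),
                                    config = synth_config()) {
  if (is.list(locus)) {
    lseq <- normalize_dna(locus$sequence)
    lchrom <- locus$chrom %||% "locus"
    lstart <- locus$start %||% 1L
  } else {
    lseq <- normalize_dna(locus)
    lchrom <- "locus"
    lstart <- 1L
  }
  .stop_if(nchar(lseq) < 40L, "locus must be at least 40 nt")
  .with_seed(seed, .simulate_pingpong_impl(lseq, lchrom, lstart, n_pairs,
                                           bias_1u, bias_10a, overlap,
                                           length_range, config))
}

.simulate_pingpong_impl <- function(lseq, lchrom, lstart, n_pairs, bias_1u,
                                    bias_10a, overlap, length_range, cfg) {
  L <- nchar(lseq)
  lmax <- max(length_range)
  # primary anchor s: needs s + lmax - 1 <= L and the responder window
  # [s + overlap - lmax, s + overlap - 1] inside the locus
  smin <- max(1L, lmax - overlap + 1L)
  smax <- L - lmax + 1L
  .stop_if(smax < smin, "locus too short for the requested read lengths")
  anchors <- smin:smax
  base_at <- substr(rep(lseq, length(anchors)), anchors, anchors)
  t_anchors <- anchors[base_at == "T"]
  o_anchors <- anchors[base_at != "T"]
  rows <- list()
  for (p in seq_len(n_pairs)) {
    want_t <- runif(1) < bias_1u
    s <- if (want_t && length(t_anchors)) {
      sample(t_anchors, 1L)
    } else if (!want_t && length(o_anchors)) {
      sample(o_anchors, 1L)
    } else {
      sample(anchors, 1L)
    }
    l1 <- sample(seq(length_range[1], length_range[2]), 1L)
    l2 <- sample(seq(length_range[1], length_range[2]), 1L)
    primary <- substr(lseq, s, s + l1 - 1L)
    if (want_t) substr(primary, 1L, 1L) <- "T" # exact even if forced fallback
    resp5 <- s + overlap - 1L # genomic position of the responder 5' end
    responder <- revcomp(substr(lseq, resp5 - l2 + 1L, resp5))
    want_a <- runif(1) < bias_10a
    if (want_a && substr(responder, 10L, 10L) != "A") {
      substr(responder, 10L, 10L) <- "A"
    } else if (!want_a && substr(responder, 10L, 10L) == "A") {
      substr(responder, 10L, 10L) <- sample(c("C", "G", "T"), 1L)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      insert = c(primary, responder),
      chrom = lchrom,
      start = c(lstart + s - 1L, lstart + resp5 - l2),
      end = c(lstart + s + l1 - 2L, lstart + resp5 - 1L),
      strand = c("+", "-"),
      role = c("primary", "responder"),
      pair = p, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$sequence <- vapply(out$insert, .assemble_read, character(1),
                         adapter3 = cfg$adapter3,
                         read_length = cfg$read_length, USE.NAMES = FALSE)
  out$quality <- strrep("h", cfg$read_length)
  out$id <- sprintf("pp%05d_%s", out$pair, out$role)
  out[, c("id", "sequence", "quality", "insert", "chrom", "start", "end",
          "strand", "role", "pair")]
}

#' Write synthetic fixtures to disk
#'
#' Dumps the generated references (FASTA, wrapped at 80 chars; the piRNA
#' catalog in RNA alphabet), the gene-to-term maps (two-column TSV), the
#' truth tables (TSV) and, when reads are given, the raw library (FASTQ,
#' offset-64 qualities).
#'
#' @param ref output of [generate_references()].
#' @param dir output directory (created if needed).
#' @param reads optional data.frame of reads from [simulate_library()].
#' @return `dir`, invisibly.
#' @export
write_synth_fixtures <- function(ref, dir, reads = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(ref$genome, file.path(dir, "genome.fa"))
  for (nm in c("miRNA", "piRNA", "rRNA", "tRNA", "snRNA", "snoRNA",
               "scRNA", "srpRNA", "repeat", "mRNA")) {
    seqs <- ref$references[[nm]]
    path <- file.path(dir, paste0(sub(":", "_", nm), ".fa"))
    if (is.null(seqs) || length(seqs) == 0L) {
      file.create(path)
    } else if (nm == "piRNA") {
      # catalogs are conventionally printed in RNA alphabet
      rna <- setNames(chartr("T", "U", seqs), names(seqs))
      writeLines(paste0(">", names(rna), "\n", rna), path)
    } else {
      write_fasta(seqs, path)
    }
  }
  .write_tsv(ref$features, file.path(dir, "features.tsv"))
  .write_tsv(ref$go_map, file.path(dir, "gene2go.tsv"))
  .write_tsv(ref$pathway_map, file.path(dir, "gene2pathway.tsv"))
  .write_tsv(ref$truth$planted_mirnas, file.path(dir, "truth_mirnas.tsv"))
  .write_tsv(ref$truth$planted_pirnas, file.path(dir, "truth_pirnas.tsv"))
  .write_tsv(ref$truth$planted_edits, file.path(dir, "truth_edits.tsv"))
  if (!is.null(reads)) write_fastq(reads, file.path(dir, "reads.fq"))
  invisible(dir)
}
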
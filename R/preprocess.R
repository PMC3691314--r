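#' Default Solexa-era adapter sequences
#'
#' The 5' adapter and 3' adapter used by the library protocol this package
#' models.
#' @return named list with `adapter5` and `adapter3`.
#' @export
default_adapters <- function() {
  list(
    adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
    adapter3 = "TCGTATGCCGTCTTCTGCTTG"
  )
}

#' Strip adapters from one read
#'
#' A prefix of the read matching a suffix of the 5' adapter (at least
#' `min_overlap` nt, exact match) is removed; the read is then truncated at
#' the leftmost position where a prefix of the 3' adapter (at least
#' `min_overlap` nt, exact match, possibly running off the read end) begins.
#' Adapter matching is exact; rejection is returned as a value, not an error.
#'
#' @param sequence read sequence (single string).
#' @param adapter5,adapter3 adapter sequences; see [default_adapters()].
#' @param min_overlap minimum exact adapter overlap in nt (default 6).
#' @return list with `insert` (string or `NA`) and `reason` (`NA` if kept,
#'   else `"adapter_dimer"` or `"no_3prime_adapter"`).
#' @export
strip_adapters <- function(sequence, adapter5, adapter3, min_overlap = 6L) {
  .stop_if(nchar(adapter5) == 0 || nchar(adapter3) == 0, "adapters must be non-empty")
  res <- .strip_adapters_vec(sequence, adapter5, adapter3, min_overlap)
  list(insert = res$insert[1], reason = res$reason[1])
}

# vectorized core used by strip_adapters() and clean_reads()
.strip_adapters_vec <- function(sequences, adapter5, adapter3, min_overlap = 6L) {
  n <- length(sequences)
  seqs <- sequences
  la5 <- nchar(adapter5)
  # longest suffix of adapter5 (>= min_overlap) that prefixes each read
  trim5 <- integer(n)
  for (k in seq(la5, min_overlap)) {
    suf <- substr(adapter5, la5 - k + 1L, la5)
    hit <- trim5 == 0L & startsWith(seqs, suf)
    trim5[hit] <- k
  }
  seqs <- substr(seqs, trim5 + 1L, nchar(seqs))
  # leftmost position where a prefix of adapter3 (>= min_overlap) starts
  len <- nchar(seqs)
  maxlen <- if (n) max(len) else 0L
  cut <- rep(NA_integer_, n)
  la3 <- nchar(adapter3)
  if (maxlen >= min_overlap) {
    for (p in seq_len(maxlen - min_overlap + 1L)) {
      todo <- is.na(cut) & len >= p + min_overlap - 1L
      if (!any(todo)) next
      k <- pmin(la3, len[todo] - p + 1L)
      frag <- substr(seqs[todo], p, p + k - 1L)
      hit <- frag == substr(adapter3, 1L, k)
      idx <- which(todo)[hit]
      cut[idx] <- p
    }
  }
  insert <- ifelse(is.na(cut), NA_character_, substr(seqs, 1L, ifelse(is.na(cut), 0L, cut - 1L)))
  reason <- rep(NA_character_, n)
  reason[is.na(cut)] <- "no_3prime_adapter"
  dimer <- !is.na(cut) & nchar(insert) == 0L
  reason[dimer] <- "adapter_dimer"
  insert[dimer] <- NA_character_
  list(insert = insert, reason = reason)
}

#' Flag a low-quality read
#'
#' Per-base scores are decoded with the offset-64 rule Q = ASCII - 64; a read
#' is low quality when the fraction of bases with Q below `q_threshold`
#' exceeds `max_bad_fraction`. The default `max_bad_fraction = 0` is the
#' strictest reading of the rule: a single base under the threshold rejects
#' the read.
#'
#' @param sequence read sequence.
#' @param quality quality string, same length, offset-64 encoded.
#' @param q_threshold quality cutoff (default 10).
#' @param max_bad_fraction tolerated fraction of sub-threshold bases.
#' @return logical.
#' @export
is_low_quality <- function(sequence, quality, q_threshold = 10L, max_bad_fraction = 0) {
  .stop_if(nchar(sequence) != nchar(quality),
           "sequence and quality strings differ in length")
  q <- utf8ToInt(quality) - 64L
  mean(q < q_threshold) > max_bad_fraction
}

.low_quality_vec <- function(sequences, qualities, q_threshold = 10L, max_bad_fraction = 0) {
  .stop_if(any(nchar(sequences) != nchar(qualities)),
           "sequence and quality strings differ in length")
  vapply(qualities, function(q) {
    mean((utf8ToInt(q) - 64L) < q_threshold) > max_bad_fraction
  }, logical(1), USE.NAMES = FALSE)
}

#' Clean raw reads
#'
#' Applies, in order: low-quality rejection (offset-64, Q < 10), adapter
#' stripping, rejection of N-containing inserts, and the 11-33 nt tag length
#' window. Each read is accounted for exactly once; the first failing filter
#' names the rejection reason.
#'
#' @param reads data.frame with `sequence` and `quality` columns
#'   (see [read_fastq()]).
#' @param adapter5,adapter3 adapters; default [default_adapters()].
#' @param length_window integer vector `c(min, max)` insert length window.
#' @param q_threshold,max_bad_fraction see [is_low_quality()].
#' @param min_overlap see [strip_adapters()].
#' @return list with `inserts` (character vector of kept insert sequences) and
#'   `summary` (list: `total_reads`, `clean_reads`, `unique_tags`,
#'   `rejected_by_reason`).
#' @export
clean_reads <- function(reads,
                        adapter5 = default_adapters()$adapter5,
                        adapter3 = default_adapters()$adapter3,
                        length_window = c(11L, 33L),
                        q_threshold = 10L, max_bad_fraction = 0,
                        min_overlap = 6L) {
  reasons <- c("low_quality", "adapter_dimer", "no_3prime_adapter",
               "contains_N", "length_window")
  rej <- setNames(integer(length(reasons)), reasons)
  n <- nrow(reads)
  if (is.null(n) || n == 0L) {
    return(list(inserts = character(0),
                summary = list(total_reads = 0L, clean_reads = 0L,
                               unique_tags = 0L, rejected_by_reason = rej)))
  }
  lowq <- .low_quality_vec(reads$sequence, reads$quality, q_threshold, max_bad_fraction)
  rej["low_quality"] <- sum(lowq)
  keep <- !lowq
  stripped <- .strip_adapters_vec(reads$sequence[keep], adapter5, adapter3, min_overlap)
  rej["adapter_dimer"] <- sum(stripped$reason == "adapter_dimer", na.rm = TRUE)
  rej["no_3prime_adapter"] <- sum(stripped$reason == "no_3prime_adapter", na.rm = TRUE)
  ins <- stripped$insert[is.na(stripped$reason)]
  hasN <- grepl("N", ins, fixed = TRUE)
  rej["contains_N"] <- sum(hasN)
  ins <- ins[!hasN]
  len <- nchar(ins)
  inwin <- len >= length_window[1] & len <= length_window[2]
  rej["length_window"] <- sum(!inwin)
  ins <- ins[inwin]
  stopifnot(length(ins) + sum(rej) == n)
  list(
    inserts = ins,
    summary = list(
      total_reads = n,
      clean_reads = length(ins),
      unique_tags = length(unique(ins)),
      rejected_by_reason = rej
    )
  )
}

#' Collapse insert sequences to unique tags with counts
#'
#' One tag per distinct sequence; counts sum to the number of inserts.
#' Output is sorted by descending count, ties broken lexicographically.
#'
#' @param inserts character vector of clean insert sequences.
#' @return data.frame with columns `sequence`, `count`.
#' @export
collapse_to_tags <- function(inserts) {
  if (length(inserts) == 0L) {
    return(data.frame(sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(inserts)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write unique tags as FASTA with rank/count headers
#'
#' Headers follow the `>tag<rank>_x<count>` convention.
#'
#' @param tags data.frame from [collapse_to_tags()].
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_tags_fasta <- function(tags, path) {
  seqs <- tags$sequence
  names(seqs) <- sprintf("tag%d_x%d", seq_len(nrow(tags)), tags$count)
  write_fasta(seqs, path)
}
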
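#' Match tags against a piRNA catalog
#'
#' A tag matches a catalog entry when it aligns within the entry (at most
#' `max_mismatch` substitutions, same orientation). Each matched entry is
#' reported with all matching tags, its most abundant tag, and its summed
#' read count; entries are sorted by total count descending. Catalogs printed
#' in RNA alphabet are handled (U mapped to T).
#'
#' @param tags data.frame of tags (`sequence`, `count`).
#' @param catalog named character vector of piRNA sequences.
#' @param max_mismatch maximum substitutions (default 1).
#' @return data.frame with columns `pirna`, `pirna_sequence`, `pirna_length`,
#'   `total_count`, `n_tags`, `top_tag`, `top_tag_length`, `top_tag_count`.
#' @export
match_pirna_catalog <- function(tags, catalog, max_mismatch = 1L) {
  catalog <- normalize_dna(catalog)
  cat_set <- Biostrings::DNAStringSet(catalog)
  rows <- list()
  for (j in seq_along(catalog)) {
    Lc <- nchar(catalog[j])
    sel <- which(nchar(tags$sequence) <= Lc & !grepl("N", tags$sequence))
    if (length(sel) == 0L) next
    hit <- vapply(sel, function(i) {
      Biostrings::countPattern(normalize_dna(tags$sequence[i]), cat_set[[j]],
                               max.mismatch = max_mismatch,
                               with.indels = FALSE) > 0L
    }, logical(1))
    sel <- sel[hit]
    if (length(sel) == 0L) next
    counts <- tags$count[sel]
    top <- sel[order(-counts, tags$sequence[sel])][1]
    rows[[length(rows) + 1L]] <- data.frame(
      pirna = names(catalog)[j], pirna_sequence = catalog[j],
      pirna_length = Lc, total_count = sum(counts), n_tags = length(sel),
      top_tag = normalize_dna(tags$sequence[top]),
      top_tag_length = nchar(tags$sequence[top]),
      top_tag_count = tags$count[top], stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(pirna = character(0), pirna_sequence = character(0),
                      pirna_length = integer(0), total_count = numeric(0),
                      n_tags = integer(0), top_tag = character(0),
                      top_tag_length = integer(0), top_tag_count = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[order(-res$total_count, res$pirna), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Positional base composition of a tag set
#'
#' Read-count-weighted base fractions at a 1-based position from the 5' end,
#' over tags long enough to have that position. Fractions sum to 1.
#'
#' @param tags data.frame (`sequence`, `count`).
#' @param position 1-based position from the 5' end.
#' @return named numeric vector over A, C, G, T.
#' @export
positional_base_bias <- function(tags, position) {
  .stop_if(position < 1, "position must be >= 1 (1-based from the 5' end)")
  sel <- nchar(tags$sequence) >= position
  .stop_if(!any(sel), "no tag reaches the requested position")
  base <- substr(normalize_dna(tags$sequence[sel]), position, position)
  w <- tags$count[sel]
  tot <- tapply(w, factor(base, levels = c("A", "C", "G", "T")), sum)
  tot[is.na(tot)] <- 0
  as.vector(tot / sum(tot)) |> setNames(c("A", "C", "G", "T"))
}

#' Ping-pong 5'-overlap signature
#'
#' For every pair of opposite-strand reads overlapping on the genome, the
#' distance between their 5' ends (plus-strand 5' end to minus-strand 5' end,
#' inclusive) is recorded; the histogram over 1..30 nt and the z-score of the
#' 10-nt bin, `z10 = (h[10] - mean(h[-10])) / sd(h[-10])`, summarize the
#' signature. Position-1 U (on plus-strand reads) and position-10 A (on
#' minus-strand reads) fractions are reported alongside.
#'
#' @param reads data.frame with columns `chrom`, `start`, `end` (1-based,
#'   inclusive), `strand`, `sequence`, and optionally `count` (default 1).
#' @param max_overlap largest overlap bin (default 30).
#' @return object of class `pingpong_signature`: list with
#'   `overlap_histogram` (named integer vector "1".."30"), `z10`,
#'   `pos1_U_fraction`, `pos10_A_fraction`, `n_pairs`.
#' @export
pingpong_overlap_signature <- function(reads, max_overlap = 30L) {
  .stop_if(!all(c("chrom", "start", "end", "strand") %in% names(reads)),
           "reads need chrom/start/end/strand columns")
  if (is.null(reads$count)) reads$count <- 1L
  h <- setNames(integer(max_overlap), as.character(seq_len(max_overlap)))
  plus <- reads[reads$strand == "+", , drop = FALSE]
  minus <- reads[reads$strand == "-", , drop = FALSE]
  npairs <- 0L
  if (nrow(plus) && nrow(minus)) {
    for (chrom in intersect(unique(plus$chrom), unique(minus$chrom))) {
      p <- plus[plus$chrom == chrom, , drop = FALSE]
      m <- minus[minus$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(p))) {
        ov <- m$start <= p$end[i] & m$end >= p$start[i]
        if (!any(ov)) next
        # 5' end of a plus read is its start; of a minus read its end
        d <- m$end[ov] - p$start[i] + 1L
        d <- d[d >= 1L & d <= max_overlap]
        for (x in d) h[x] <- h[x] + 1L
        npairs <- npairs + length(d)
      }
    }
  }
  others <- h[-10L]
  z10 <- if (npairs == 0L || sd(others) == 0) NA_real_ else
    (h[[10L]] - mean(others)) / sd(others)
  pos1 <- if (nrow(plus)) positional_base_bias(
    data.frame(sequence = plus$sequence, count = plus$count), 1L)[["T"]] else NA_real_
  pos10 <- if (nrow(minus) && any(nchar(minus$sequence) >= 10L)) positional_base_bias(
    data.frame(sequence = minus$sequence, count = minus$count), 10L)[["A"]] else NA_real_
  structure(
    list(overlap_histogram = h, z10 = z10, pos1_U_fraction = pos1,
         pos10_A_fraction = pos10, n_pairs = npairs),
    class = "pingpong_signature"
  )
}

#' @export
print.pingpong_signature <- function(x, ...) {
  mode_bin <- if (x$n_pairs > 0) names(which.max(x$overlap_histogram)) else NA
  cat(sprintf(
    "ping-pong signature: %d overlapping pairs, modal 5'-overlap = %s nt, z10 = %s\n",
    x$n_pairs, mode_bin,
    if (is.na(x$z10)) "undefined" else sprintf("%.2f", x$z10)))
  cat(sprintf("  position-1 U fraction (sense) = %s, position-10 A fraction (antisense) = %s\n",
              format(x$pos1_U_fraction, digits = 3),
              format(x$pos10_A_fraction, digits = 3)))
  invisible(x)
}

#' Abundance share of the top-n entries of an expression table
#'
#' @param counts numeric vector of per-entry read counts (or a data.frame
#'   with a `total_count` or `reads` column).
#' @param n number of top entries.
#' @return fraction in (0, 1].
#' @export
top_share <- function(counts, n) {
  if (is.data.frame(counts)) {
    counts <- if (!is.null(counts$total_count)) counts$total_count else counts$reads
  }
  .stop_if(length(counts) == 0L, "empty expression table")
  .stop_if(n < 1, "n must be >= 1")
  sum(sort(counts, decreasing = TRUE)[seq_len(min(n, length(counts)))]) / sum(counts)
}

#' Classify piRNA target classes by antisense alignment
#'
#' Each piRNA is assigned the class of its best antisense alignment (fewest
#' mismatches, full piRNA length, identity at least `min_identity`) against a
#' labeled repeat/transcript reference; unassigned piRNAs are excluded from
#' the returned fractions.
#'
#' @param pirnas character vector of piRNA sequences.
#' @param reference named character vector of reference sequences.
#' @param classes character vector of class labels, parallel to `reference`
#'   (e.g. `"retrotransposon:LINE1"`, `"retrotransposon:LTR"`, `"repeat"`,
#'   `"mRNA"`, `"other"`).
#' @param min_identity minimum identity over the full piRNA (default 0.9).
#' @return list with `assignments` (data.frame: `pirna_sequence`, `class`,
#'   `mismatches`) and `fractions` (named numeric vector over assigned
#'   classes, summing to 1).
#' @export
classify_pirna_targets <- function(pirnas, reference, classes,
                                   min_identity = 0.9) {
  .stop_if(length(reference) != length(classes),
           "reference and classes must be parallel")
  pirnas <- normalize_dna(pirnas)
  ref_set <- Biostrings::DNAStringSet(normalize_dna(reference))
  rows <- list()
  for (s in pirnas) {
    L <- nchar(s)
    max_mm <- floor((1 - min_identity) * L)
    query <- revcomp(s) # antisense alignment
    best_mm <- NA_integer_; best_class <- NA_character_
    for (j in seq_along(ref_set)) {
      if (Biostrings::width(ref_set)[j] < L) next
      for (mm in 0:max_mm) {
        if (!is.na(best_mm) && mm >= best_mm) break
        if (Biostrings::countPattern(query, ref_set[[j]], max.mismatch = mm,
                                     with.indels = FALSE) > 0L) {
          best_mm <- mm; best_class <- classes[j]
          break
        }
      }
      if (!is.na(best_mm) && best_mm == 0L) break
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pirna_sequence = s,
      class = if (is.na(best_class)) "unassigned" else best_class,
      mismatches = best_mm, stringsAsFactors = FALSE
    )
  }
  assignments <- do.call(rbind, rows)
  assigned <- assignments$class[assignments$class != "unassigned"]
  fractions <- if (length(assigned)) {
    tab <- table(assigned)
    setNames(as.numeric(tab) / length(assigned), names(tab))
  } else {
    numeric(0)
  }
  list(assignments = assignments, fractions = fractions)
}
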
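#' Build a genome index for tag mapping
#'
#' Wraps the genome (named chromosome sequences) as a `DNAStringSet` together
#' with its reverse complement so tags can be matched on both strands with at
#' most one substitution. Stands in for a short-read aligner at desk scale.
#'
#' @param genome named character vector or `DNAStringSet` of chromosomes.
#' @return object of class `genome_index`.
#' @export
genome_index <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(normalize_dna(genome))
  .stop_if(is.null(names(genome)), "chromosomes must be named")
  structure(
    list(fwd = genome, rev = Biostrings::reverseComplement(genome),
         lengths = setNames(Biostrings::width(genome), names(genome))),
    class = "genome_index"
  )
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x$fwd), "chromosome(s),",
      sum(x$lengths), "bp total\n")
  invisible(x)
}

#' Map one tag to the genome with at most one mismatch
#'
#' Finds all genomic positions (both strands) where the tag aligns with at
#' most `max_mismatch` substitutions and no indels. Tags containing N return
#' an empty hit list.
#'
#' @param tag tag sequence (single string).
#' @param index a [genome_index()].
#' @param max_mismatch maximum substitutions (default 1).
#' @return data.frame with columns `chrom`, `start` (1-based), `end`,
#'   `strand`, `mismatches`.
#' @export
map_tag <- function(tag, index, max_mismatch = 1L) {
  .stop_if(!inherits(index, "genome_index"), "index must be a genome_index")
  tag <- normalize_dna(tag)
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (grepl("N", tag, fixed = TRUE) || nchar(tag) == 0L) return(empty)
  pat <- Biostrings::DNAString(tag)
  L <- nchar(tag)
  out <- vector("list", 2L * length(index$fwd))
  k <- 0L
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") index$fwd else index$rev
    for (ci in seq_along(subj)) {
      m <- Biostrings::matchPattern(pat, subj[[ci]],
                                    max.mismatch = max_mismatch,
                                    with.indels = FALSE)
      if (length(m) == 0L) next
      st <- BiocGenerics::start(m)
      # mismatch count verified by direct comparison
      mm <- vapply(seq_along(m), function(i) {
        Biostrings::neditStartingAt(pat, subj[[ci]], starting.at = st[i],
                                    with.indels = FALSE)
      }, integer(1))
      keep <- mm <= max_mismatch
      if (!any(keep)) next
      st <- st[keep]; mm <- mm[keep]
      clen <- index$lengths[[ci]]
      if (strand == "+") {
        gstart <- st
      } else {
        gstart <- clen - (st + L - 1L) + 1L
      }
      k <- k + 1L
      out[[k]] <- data.frame(chrom = names(index$fwd)[ci], start = gstart,
                             end = gstart + L - 1L, strand = strand,
                             mismatches = as.integer(mm),
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(empty)
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# category priority of the annotation cascade (Table-1 row order inside the
# non-coding block)
.cascade_order <- function() {
  c("miRNA", "piRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "srpRNA",
    "repeat", "mRNA")
}

# does `tag` align within any sequence of `refs` with <= max_mismatch
# substitutions, same orientation?
.matches_reference <- function(tag, refs, max_mismatch = 1L) {
  if (length(refs) == 0L) return(FALSE)
  if (nchar(tag) == 0L || grepl("N", tag, fixed = TRUE)) return(FALSE)
  wide <- Biostrings::width(refs) >= nchar(tag)
  if (!any(wide)) return(FALSE)
  hits <- Biostrings::vcountPattern(tag, refs[wide], max.mismatch = max_mismatch,
                                    with.indels = FALSE)
  any(hits > 0L)
}

#' Assign a tag to a small-RNA category via the priority cascade
#'
#' A tag is checked against reference sets in the fixed priority order
#' miRNA, piRNA, rRNA, tRNA, snRNA, snoRNA, scRNA, srpRNA, repeat, mRNA;
#' the first set in which the tag aligns (within a reference sequence, at
#' most one mismatch, same orientation) wins. Tags matching nothing are
#' `unannotated`. The load order of `references` never changes the result.
#'
#' @param tag tag sequence.
#' @param references named list of reference sets (character vectors or
#'   `DNAStringSet`s); names from the category list above. Missing categories
#'   are treated as empty.
#' @param max_mismatch maximum substitutions in a reference alignment.
#' @return category string.
#' @export
classify_tag <- function(tag, references, max_mismatch = 1L) {
  tag <- normalize_dna(tag)
  refs <- .prepare_references(references)
  for (cat in .cascade_order()) {
    if (!is.null(refs[[cat]]) && .matches_reference(tag, refs[[cat]], max_mismatch)) {
      return(cat)
    }
  }
  "unannotated"
}

.prepare_references <- function(references) {
  lapply(references, function(r) {
    if (is.character(r)) Biostrings::DNAStringSet(normalize_dna(r)) else r
  })
}

#' Annotate a tag set: map to the genome and run the category cascade
#'
#' @param tags data.frame from [collapse_to_tags()].
#' @param index a [genome_index()], or `NULL` to skip mapping.
#' @param references named list of category reference sets (see
#'   [classify_tag()]).
#' @param max_mismatch maximum substitutions.
#' @return data.frame with one row per tag: `sequence`, `count`, `category`,
#'   `n_hits`; genomic hits in `attr(, "hits")` (list parallel to rows).
#' @export
annotate_tags <- function(tags, index = NULL, references = list(), max_mismatch = 1L) {
  refs <- .prepare_references(references)
  n <- nrow(tags)
  cats <- character(n)
  hits <- vector("list", n)
  for (i in seq_len(n)) {
    s <- normalize_dna(tags$sequence[i])
    hits[[i]] <- if (is.null(index)) NULL else map_tag(s, index, max_mismatch)
    cat_i <- "unannotated"
    for (cat in .cascade_order()) {
      if (!is.null(refs[[cat]]) && .matches_reference(s, refs[[cat]], max_mismatch)) {
        cat_i <- cat
        break
      }
    }
    cats[i] <- cat_i
  }
  out <- data.frame(sequence = tags$sequence, count = tags$count,
                    category = cats,
                    n_hits = vapply(hits, function(h) if (is.null(h)) 0L else nrow(h),
                                    integer(1)),
                    stringsAsFactors = FALSE)
  attr(out, "hits") <- hits
  out
}

#' Category summary table (unique tags and read counts per category)
#'
#' One row per category plus a `Total` row; unique-tag and read counts are
#' also given as percentages of the totals. Percentages sum to 100 within
#' rounding.
#'
#' @param records data.frame from [annotate_tags()].
#' @return data.frame with columns `category`, `unique_tags`,
#'   `unique_tags_percent`, `total_reads`, `total_reads_percent`.
#' @export
summarize_categories <- function(records) {
  cats <- c(.cascade_order(), "unannotated")
  present <- cats[cats %in% records$category]
  rows <- lapply(present, function(cat) {
    sel <- records$category == cat
    data.frame(category = cat, unique_tags = sum(sel),
               total_reads = sum(records$count[sel]), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(
    data.frame(category = "Total", unique_tags = nrow(records),
               total_reads = sum(records$count), stringsAsFactors = FALSE)
  )))
  tot_u <- df$unique_tags[df$category == "Total"]
  tot_r <- df$total_reads[df$category == "Total"]
  df$unique_tags_percent <- if (tot_u > 0) 100 * df$unique_tags / tot_u else 0
  df$total_reads_percent <- if (tot_r > 0) 100 * df$total_reads / tot_r else 0
  df[, c("category", "unique_tags", "unique_tags_percent",
         "total_reads", "total_reads_percent")]
}

#' Chromosome distribution of mapped reads
#'
#' Multi-hit tags contribute their read count to each chromosome hit, divided
#' by the number of hits (fractional assignment), so the distribution sums
#' exactly to the total mapped read count.
#'
#' @param records data.frame from [annotate_tags()] (with mapping hits).
#' @return named numeric vector, chromosome -> read count.
#' @export
chromosome_distribution <- function(records) {
  hits <- attr(records, "hits")
  .stop_if(is.null(hits), "records carry no mapping hits")
  acc <- list()
  for (i in seq_len(nrow(records))) {
    h <- hits[[i]]
    if (is.null(h) || nrow(h) == 0L) next
    w <- records$count[i] / nrow(h)
    for (chrom in h$chrom) {
      acc[[chrom]] <- (if (is.null(acc[[chrom]])) 0 else acc[[chrom]]) + w
    }
  }
  unlist(acc)[order(names(acc))]
}

#' Quantify known miRNAs from annotated tags
#'
#' Each miRNA-category tag is assigned to its best catalog match (fewest
#' mismatches; ties broken by catalog name) and read counts are summed per
#' catalog entry. Only detected miRNAs appear in the table.
#'
#' @param records data.frame from [annotate_tags()].
#' @param mirna_catalog named character vector of mature miRNA sequences.
#' @param max_mismatch maximum substitutions for a catalog alignment.
#' @return data.frame with columns `mirna`, `reads`, `unique_tags`, sorted by
#'   descending reads (ties by name).
#' @export
quantify_known_mirnas <- function(records, mirna_catalog, max_mismatch = 1L) {
  catalog <- normalize_dna(mirna_catalog)
  cat_set <- Biostrings::DNAStringSet(catalog)
  nm <- names(catalog)
  sel <- which(records$category == "miRNA")
  acc_reads <- setNames(numeric(length(catalog)), nm)
  acc_tags <- setNames(integer(length(catalog)), nm)
  for (i in sel) {
    s <- normalize_dna(records$sequence[i])
    wide <- which(Biostrings::width(cat_set) >= nchar(s))
    if (length(wide) == 0L) next
    mm <- rep(NA_integer_, length(catalog))
    for (j in wide) {
      if (Biostrings::countPattern(s, cat_set[[j]], max.mismatch = 0L) > 0L) {
        mm[j] <- 0L
      } else if (max_mismatch >= 1L &&
                 Biostrings::countPattern(s, cat_set[[j]], max.mismatch = max_mismatch,
                                          with.indels = FALSE) > 0L) {
        mm[j] <- 1L
      }
    }
    if (all(is.na(mm))) next
    best <- which(mm == min(mm, na.rm = TRUE))
    best <- best[order(nm[best])][1]
    acc_reads[best] <- acc_reads[best] + records$count[i]
    acc_tags[best] <- acc_tags[best] + 1L
  }
  det <- acc_tags > 0L
  df <- data.frame(mirna = nm[det], reads = acc_reads[det],
                   unique_tags = acc_tags[det], stringsAsFactors = FALSE)
  df <- df[order(-df$reads, df$mirna), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Top rows of an expression table
#'
#' @param table data.frame sorted or sortable by a `reads` column.
#' @param n number of rows to keep.
#' @return the top `n` rows by descending reads (deterministic tie-break by
#'   first column).
#' @export
top_n_expressed <- function(table, n) {
  .stop_if(n < 1, "n must be >= 1")
  ord <- order(-table$reads, table[[1]])
  head(table[ord, , drop = FALSE], n)
}

#' Detect candidate miRNA editing events
#'
#' For each catalog miRNA, exact-match and single-mismatch tags are pooled;
#' a position is reported when the mismatch reads at that position exceed
#' `min_fraction` of the pooled reads. The first and last `end_exclude`
#' positions are skipped because 5'/3' end heterogeneity confounds them.
#'
#' @param records data.frame from [annotate_tags()].
#' @param mirna_catalog named character vector of mature miRNA sequences.
#' @param min_fraction minimum edited-read fraction (default 0.10, strict >).
#' @param end_exclude positions excluded at each end (default 2).
#' @return data.frame with columns `mirna`, `position` (1-based in the
#'   catalog sequence), `ref_base`, `alt_base`, `edited_reads`, `total_reads`,
#'   `edited_fraction`.
#' @export
detect_editing <- function(records, mirna_catalog, min_fraction = 0.10,
                           end_exclude = 2L) {
  catalog <- normalize_dna(mirna_catalog)
  out <- list()
  sel <- which(records$category == "miRNA")
  for (j in seq_along(catalog)) {
    ref <- catalog[j]
    L <- nchar(ref)
    refv <- strsplit(ref, "")[[1]]
    total <- 0
    mism <- list() # key: position|alt
    for (i in sel) {
      s <- normalize_dna(records$sequence[i])
      ls <- nchar(s)
      if (ls > L) next
      # alignment offsets of s within ref at <= 1 substitution
      sv <- strsplit(s, "")[[1]]
      for (off in 0:(L - ls)) {
        refseg <- refv[(off + 1):(off + ls)]
        d <- which(sv != refseg)
        if (length(d) == 0L) {
          total <- total + records$count[i]
          break
        } else if (length(d) == 1L) {
          pos <- off + d
          total <- total + records$count[i]
          key <- paste0(pos, "|", refv[pos], ">", sv[d])
          mism[[key]] <- (if (is.null(mism[[key]])) 0 else mism[[key]]) + records$count[i]
          break
        }
      }
    }
    if (total == 0 || length(mism) == 0L) next
    for (key in names(mism)) {
      parts <- strsplit(key, "[|>]")[[1]]
      pos <- as.integer(parts[1])
      if (pos <= end_exclude || pos > L - end_exclude) next
      frac <- mism[[key]] / total
      if (frac > min_fraction) {
        out[[length(out) + 1L]] <- data.frame(
          mirna = names(catalog)[j], position = pos,
          ref_base = parts[2], alt_base = parts[3],
          edited_reads = mism[[key]], total_reads = total,
          edited_fraction = frac, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(mirna = character(0), position = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      edited_reads = numeric(0), total_reads = numeric(0),
                      edited_fraction = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
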
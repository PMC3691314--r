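#' Read a FASTQ file of raw reads (offset-64 qualities)
#'
#' Reads are returned as a data.frame with one row per read. Quality strings
#' are kept verbatim; decode them with [decode_quality()], which applies the
#' Solexa-era rule Q = ASCII code - 64.
#'
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- as.character(S4Vectors::mcols(x)$qualities)
  data.frame(
    id = sub("\\s.*$", "", names(x)),
    sequence = as.character(x),
    quality = q,
    stringsAsFactors = FALSE
  )
}

#' Write raw reads to FASTQ (offset-64 qualities)
#'
#' Each record's description carries a `qoffset=64` token so downstream users
#' know the encoding.
#'
#' @param reads data.frame with columns `sequence` and `quality` (and
#'   optionally `id`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  .stop_if(!all(c("sequence", "quality") %in% names(reads)),
           "reads must have 'sequence' and 'quality' columns")
  ids <- if (!is.null(reads$id)) reads$id else sprintf("read%06d", seq_len(nrow(reads)))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- paste0(ids, " qoffset=64")
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality)
  )
  invisible(path)
}

#' Decode an offset-64 quality string
#'
#' Per-base quality is Q = (ASCII character code) - 64, so characters decode
#' to scores in \[-64, 62\].
#'
#' @param quality character vector of quality strings.
#' @return list of integer vectors, one per input string.
#' @export
decode_quality <- function(quality) {
  lapply(quality, function(q) {
    if (nchar(q) == 0) return(integer(0))
    utf8ToInt(q) - 64L
  })
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are normalized to uppercase DNA (U mapped to T).
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- normalize_dna(as.character(x))
  names(out) <- names(x)
  out
}

#' Write named sequences to FASTA (wrapped at 80 characters)
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(normalize_dna(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

# tab-separated table writer shared by pipeline stages
.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
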
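#' Fold enrichment ratio (E-ratio)
#'
#' With N annotated genes in the genome, n of them carrying a specific term,
#' M annotated genes among the predicted targets and m of those carrying the
#' term, the fold enrichment is `(m/M) / (n/N)`.
#'
#' @param m,M,n,N enrichment counts (see Details).
#' @return numeric ratio; 0 when `m = 0`.
#' @export
e_ratio <- function(m, M, n, N) {
  .stop_if(M <= 0 || n <= 0 || N <= 0, "M, n and N must be positive")
  (m / M) / (n / N)
}

.check_enrichment_input <- function(m, M, n, N) {
  .stop_if(any(c(m, M, n, N) < 0), "counts must be non-negative")
  .stop_if(M > N || n > N, "M and n cannot exceed N")
  .stop_if(m > min(n, M), "m cannot exceed min(n, M)")
  .stop_if(N - M - n + m < 0, "negative cell in the 2x2 table")
}

#' Hypergeometric upper-tail p-value
#'
#' P(X >= m) where X counts term-annotated genes in a draw of M genes from a
#' universe of N containing n term-annotated genes.
#'
#' @inheritParams e_ratio
#' @return p-value in (0, 1].
#' @export
hypergeometric_tail_p <- function(m, M, n, N) {
  .check_enrichment_input(m, M, n, N)
  if (m <= 0) return(1)
  stats::phyper(m - 1, n, N - n, M, lower.tail = FALSE)
}

#' One-sided Fisher's exact test for enrichment
#'
#' One-sided (greater) Fisher's exact p on the 2x2 table
#' `(m, M - m; n - m, N - M - n + m)`; identical to the hypergeometric upper
#' tail.
#'
#' @inheritParams e_ratio
#' @return p-value in (0, 1].
#' @export
fisher_exact_p <- function(m, M, n, N) {
  .check_enrichment_input(m, M, n, N)
  tab <- matrix(c(m, M - m, n - m, N - M - n + m), nrow = 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Term enrichment of target genes against a gene universe
#'
#' One result per term with at least one target gene. The background counts
#' are taken over annotated genes only: N = annotated genes in the universe,
#' n = universe genes with the term, M = annotated target genes, m = target
#' genes with the term. Significance uses strict thresholds as printed:
#' E-ratio > `min_e_ratio` and p < `max_p` (GO uses 2/0.05, pathways
#' 1.5/0.05). Results are sorted by E-ratio descending, ties by ascending p,
#' then term id. No multiple-testing correction is applied by default; set
#' `adjust = "BH"` for Benjamini-Hochberg adjusted significance.
#'
#' @param gene2term data.frame with columns `gene`, `term` (and optionally
#'   `description`).
#' @param targets character vector of target gene ids (subset of `universe`).
#' @param universe character vector of all gene ids.
#' @param min_e_ratio E-ratio threshold (strict >); 2 for GO, 1.5 for pathways.
#' @param max_p p-value threshold (strict <).
#' @param test `"hypergeometric"` or `"fisher"` (identical results).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with columns `term`, `description`, `m`, `M`, `n`, `N`,
#'   `target_percent`, `genome_percent`, `e_ratio`, `p_value`, `significant`.
#' @export
enrich <- function(gene2term, targets, universe, min_e_ratio = 2,
                   max_p = 0.05, test = c("hypergeometric", "fisher"),
                   adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  .stop_if(length(universe) == 0L, "empty gene universe")
  .stop_if(!all(targets %in% universe), "targets must be a subset of the universe")
  ann <- gene2term[gene2term$gene %in% universe, , drop = FALSE]
  annotated <- unique(ann$gene)
  N <- length(annotated)
  .stop_if(N == 0L, "no annotated gene in the universe")
  targ_ann <- intersect(targets, annotated)
  M <- length(targ_ann)
  terms <- unique(ann$term[ann$gene %in% targ_ann])
  rows <- lapply(terms, function(tm) {
    genes_tm <- unique(ann$gene[ann$term == tm])
    n <- length(genes_tm)
    m <- length(intersect(genes_tm, targ_ann))
    p <- if (test == "fisher") fisher_exact_p(m, M, n, N) else
      hypergeometric_tail_p(m, M, n, N)
    desc <- if (!is.null(ann$description)) ann$description[ann$term == tm][1] else tm
    data.frame(term = tm, description = desc, m = m, M = M, n = n, N = N,
               target_percent = 100 * m / M, genome_percent = 100 * n / N,
               e_ratio = e_ratio(m, M, n, N), p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  pp <- if (adjust == "BH") p.adjust(res$p_value, "BH") else res$p_value
  res$significant <- res$e_ratio > min_e_ratio & pp < max_p
  res <- res[order(-res$e_ratio, res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
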
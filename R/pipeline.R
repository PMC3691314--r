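#' Pipeline configuration with study-default thresholds
#'
#' Collects every stage threshold at its default: quality cutoff Q < 10,
#' tag length window 11-33 nt, at most 1 mapping mismatch, novel-miRNA read
#' cutoff 45, precursor energy cutoff -18 kcal/mol and target duplex cutoff
#' -20 kcal/mol, alignment score cutoff 140, E-ratio cutoffs 2 (GO) and 1.5
#' (pathway), p < 0.05. Stage toggles allow skipping downstream stages.
#'
#' @param seed integer seed driving the synthetic stage and all randomness.
#' @param ... overrides for any field.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    synth = synth_config(),
    q_threshold = 10L, max_bad_fraction = 0,
    length_window = c(11L, 33L),
    max_mismatch = 1L,
    min_novel_count = 45L,
    max_precursor_energy = -18,
    max_duplex_energy = -20,
    min_target_score = 140,
    go_min_e_ratio = 2, pathway_min_e_ratio = 1.5, max_p = 0.05,
    pirna_size_window = c(24L, 32L),
    top_n = 10L,
    stages = c(pirna = TRUE, discover = TRUE, targets = TRUE, enrich = TRUE)
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full small-RNA profiling pipeline on synthetic data
#'
#' Executes synth, clean, annotate, and (per stage toggles) novel-miRNA
#' discovery, piRNA characterization, target prediction and GO/pathway
#' enrichment. Every stage writes its table to `out_dir` (when given) and the
#' returned report aggregates: the cleaning summary, the category summary
#' table, the per-chromosome read distribution, the top-10 known miRNAs, the
#' top piRNAs with their most abundant tags, the novel-miRNA candidate
#' table, editing events, target sites and the enrichment tables. The log
#' records every threshold used and the seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for stage tables.
#' @return list of class `srna_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  cfg <- config
  log <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
  }
  say("seed=%d", cfg$seed)
  say("thresholds: q<%d window=%d-%d mismatch<=%d novel_count>=%d energy<=%.1f duplex<%.1f score>%.0f e_ratio>%.2f/%.2f p<%.2f",
      cfg$q_threshold, cfg$length_window[1], cfg$length_window[2],
      cfg$max_mismatch, cfg$min_novel_count, cfg$max_precursor_energy,
      cfg$max_duplex_energy, cfg$min_target_score, cfg$go_min_e_ratio,
      cfg$pathway_min_e_ratio, cfg$max_p)

  # --- synth -------------------------------------------------------------
  ref <- generate_references(cfg$seed, cfg$synth)
  lib <- simulate_library(ref$truth, seed = cfg$seed + 1L,
                          error_rate = cfg$synth$error_rate,
                          contamination = cfg$synth$contamination,
                          frac_low_quality = cfg$synth$frac_low_quality,
                          config = cfg$synth)
  pp <- list()
  loci <- ref$features[ref$features$class == "pirna_locus", , drop = FALSE]
  for (i in seq_len(nrow(loci))) {
    lrow <- loci[i, ]
    lseq <- substr(ref$genome[[lrow$chrom]], lrow$start, lrow$end)
    if (lrow$strand == "-") lseq <- revcomp(lseq)
    pp[[i]] <- simulate_pingpong_reads(
      list(sequence = lseq, chrom = lrow$chrom, start = lrow$start),
      n_pairs = cfg$synth$pingpong_pairs_per_locus,
      seed = cfg$seed + 100L + i,
      bias_1u = cfg$synth$bias_1u, bias_10a = cfg$synth$bias_10a,
      config = cfg$synth
    )
  }
  pp_reads <- if (length(pp)) do.call(rbind, pp) else NULL
  raw <- rbind(lib[, c("id", "sequence", "quality")],
               if (!is.null(pp_reads)) pp_reads[, c("id", "sequence", "quality")])
  say("synth: %d raw reads (%d library + %d ping-pong)", nrow(raw), nrow(lib),
      if (is.null(pp_reads)) 0L else nrow(pp_reads))

  # --- clean -------------------------------------------------------------
  cleaned <- clean_reads(raw, adapter5 = cfg$synth$adapter5,
                         adapter3 = cfg$synth$adapter3,
                         length_window = cfg$length_window,
                         q_threshold = cfg$q_threshold,
                         max_bad_fraction = cfg$max_bad_fraction)
  tags <- collapse_to_tags(cleaned$inserts)
  say("clean: %d/%d reads kept, %d unique tags",
      cleaned$summary$clean_reads, cleaned$summary$total_reads, nrow(tags))

  # --- annotate ----------------------------------------------------------
  idx <- genome_index(ref$genome)
  cascade_refs <- ref$references[c("miRNA", "piRNA", "rRNA", "tRNA", "snRNA",
                                   "snoRNA", "scRNA", "srpRNA", "repeat",
                                   "mRNA")]
  records <- annotate_tags(tags, idx, cascade_refs,
                           max_mismatch = cfg$max_mismatch)
  categories <- summarize_categories(records)
  chrom_dist <- chromosome_distribution(records)
  mirna_expr <- quantify_known_mirnas(records, ref$references$miRNA,
                                      max_mismatch = cfg$max_mismatch)
  top_mirnas <- top_n_expressed(mirna_expr, cfg$top_n)
  editing <- detect_editing(records, ref$references$miRNA)
  say("annotate: %d tags mapped, categories: %s",
      sum(records$n_hits > 0),
      paste(categories$category[-nrow(categories)], collapse = ","))

  # --- novel miRNA discovery --------------------------------------------
  discovery <- NULL
  if (isTRUE(cfg$stages[["discover"]])) {
    un <- records[records$category == "unannotated", c("sequence", "count")]
    discovery <- predict_novel_mirnas(un, idx, ref$genome,
                                      min_count = cfg$min_novel_count,
                                      max_energy = cfg$max_precursor_energy)
    say("discover: %d candidates evaluated, %d accepted",
        nrow(discovery$table), length(discovery$accepted))
  }

  # --- piRNA analysis ----------------------------------------------------
  pirna <- NULL
  if (isTRUE(cfg$stages[["pirna"]])) {
    hits_list <- attr(records, "hits")
    size_ok <- nchar(records$sequence) >= cfg$pirna_size_window[1] &
      nchar(records$sequence) <= cfg$pirna_size_window[2]
    pir_hits <- match_pirna_catalog(records[records$category == "piRNA",
                                            c("sequence", "count")],
                                    ref$references$piRNA,
                                    max_mismatch = cfg$max_mismatch)
    # strand-aware mapped reads in the piRNA size class for the signature
    mapped <- list()
    for (i in which(size_ok & records$n_hits > 0)) {
      h <- hits_list[[i]]
      h$sequence <- records$sequence[i]
      h$count <- records$count[i]
      h$is_catalog <- records$category[i] == "piRNA"
      mapped[[length(mapped) + 1L]] <- h
    }
    mapped <- if (length(mapped)) do.call(rbind, mapped) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 strand = character(0), sequence = character(0),
                 count = integer(0), is_catalog = logical(0))
    # orient reads by the piRNA annotation: catalog-matched reads define the
    # sense strand of their region; regions transcribed from the minus strand
    # are mirrored so "+" always means sense and 5' ends sit at `start`
    signature <- pingpong_overlap_signature(.orient_by_sense(mapped))
    share <- if (nrow(pir_hits)) top_share(pir_hits, cfg$top_n) else NA_real_
    tclass <- classify_pirna_targets(
      ref$references$piRNA,
      c(ref$references$`repeat`, ref$references$mRNA),
      c(unname(ref$references$repeat_classes),
        rep("mRNA", length(ref$references$mRNA)))
    )
    pirna <- list(hits = pir_hits, signature = signature,
                  top_share = share, target_classes = tclass$fractions)
    say("pirna: %d catalog entries detected, top-%d share %.3f, z10=%.2f",
        nrow(pir_hits), cfg$top_n, share, signature$z10)
  }

  # --- target prediction -------------------------------------------------
  targets <- NULL
  if (isTRUE(cfg$stages[["targets"]])) {
    top_seq <- setNames(
      ref$references$miRNA[top_mirnas$mirna],
      top_mirnas$mirna
    )
    targets <- predict_targets(top_seq, ref$references$mRNA,
                               max_energy = cfg$max_duplex_energy,
                               min_score = cfg$min_target_score)
    say("targets: %d sites evaluated, %d passing, %d genes",
        nrow(targets$sites), sum(targets$sites$passed), nrow(targets$genes))
  }

  # --- enrichment --------------------------------------------------------
  enrichment <- NULL
  if (isTRUE(cfg$stages[["enrich"]]) && !is.null(targets) &&
      nrow(targets$genes) > 0) {
    universe <- sprintf("GENE%04d", seq_len(cfg$synth$n_genes))
    go <- enrich(ref$go_map, targets$genes$gene, universe,
                 min_e_ratio = cfg$go_min_e_ratio, max_p = cfg$max_p)
    pw <- enrich(ref$pathway_map, targets$genes$gene, universe,
                 min_e_ratio = cfg$pathway_min_e_ratio, max_p = cfg$max_p,
                 test = "fisher")
    enrichment <- list(go = go, pathway = pw)
    say("enrich: %d GO terms (%d significant), %d pathways (%d significant)",
        nrow(go), sum(go$significant), nrow(pw), sum(pw$significant))
  }

  report <- structure(
    list(
      config = cfg, reference = ref, cleaning = cleaned$summary,
      tags = tags, records = records, categories = categories,
      chromosome_distribution = chrom_dist, mirna_expression = mirna_expr,
      top_mirnas = top_mirnas, editing = editing, discovery = discovery,
      pirna = pirna, targets = targets, enrichment = enrichment, log = log
    ),
    class = "srna_report"
  )
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

# flip reads lying in regions whose sense strand (defined by catalog-matched
# reads) is "-": mirrored coordinates keep all pair overlaps but give the
# transcript orientation the signature's 1U/10A conventions assume
.orient_by_sense <- function(mapped) {
  if (nrow(mapped) == 0L || !any(mapped$is_catalog)) return(mapped)
  sense <- mapped[mapped$is_catalog, , drop = FALSE]
  # the signature is a statement about the piRNA annotation: restrict to
  # reads overlapping a catalog-matched region
  keep <- vapply(seq_len(nrow(mapped)), function(i) {
    any(sense$chrom == mapped$chrom[i] & sense$start <= mapped$end[i] &
          mapped$start[i] <= sense$end)
  }, logical(1))
  out <- mapped[keep, , drop = FALSE]
  for (i in seq_len(nrow(out))) {
    ov <- sense$chrom == out$chrom[i] & sense$start <= out$end[i] &
      out$start[i] <= sense$end
    sense_strand <- names(which.max(table(sense$strand[ov])))
    if (sense_strand == "-") {
      s <- out$start[i]; e <- out$end[i]
      out$start[i] <- -e
      out$end[i] <- -s
      out$strand[i] <- if (out$strand[i] == "+") "-" else "+"
      out$chrom[i] <- paste0(out$chrom[i], ":flipped")
    }
  }
  out
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(report$categories, file.path(out_dir, "categories.tsv"))
  .write_tsv(data.frame(chromosome = names(report$chromosome_distribution),
                        reads = as.numeric(report$chromosome_distribution)),
             file.path(out_dir, "chromosome_distribution.tsv"))
  .write_tsv(report$top_mirnas, file.path(out_dir, "top_mirnas.tsv"))
  .write_tsv(report$editing, file.path(out_dir, "editing.tsv"))
  write_tags_fasta(report$tags, file.path(out_dir, "tags.fa"))
  if (!is.null(report$discovery)) {
    .write_tsv(report$discovery$table, file.path(out_dir, "novel_candidates.tsv"))
    .write_tsv(report$discovery$heterogeneity,
               file.path(out_dir, "novel_heterogeneity.tsv"))
  }
  if (!is.null(report$pirna)) {
    .write_tsv(report$pirna$hits, file.path(out_dir, "pirna_hits.tsv"))
    .write_tsv(data.frame(overlap = seq_along(report$pirna$signature$overlap_histogram),
                          pairs = as.integer(report$pirna$signature$overlap_histogram)),
               file.path(out_dir, "pingpong_histogram.tsv"))
  }
  if (!is.null(report$targets)) {
    .write_tsv(report$targets$sites, file.path(out_dir, "target_sites.tsv"))
    .write_tsv(report$targets$genes, file.path(out_dir, "target_genes.tsv"))
  }
  if (!is.null(report$enrichment)) {
    .write_tsv(report$enrichment$go, file.path(out_dir, "enrichment_go.tsv"))
    .write_tsv(report$enrichment$pathway,
               file.path(out_dir, "enrichment_pathway.tsv"))
  }
  writeLines(report$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}

#' @export
print.srna_report <- function(x, ...) {
  cat("small RNA profiling report (seed", x$config$seed, ")\n")
  cat(sprintf("  reads: %d total, %d clean, %d unique tags\n",
              x$cleaning$total_reads, x$cleaning$clean_reads, nrow(x$tags)))
  cat("  category summary:\n")
  print(x$categories, row.names = FALSE, digits = 3)
  if (!is.null(x$discovery)) {
    cat(sprintf("  novel miRNAs accepted: %d\n", length(x$discovery$accepted)))
  }
  if (!is.null(x$pirna)) {
    cat(sprintf("  piRNA: top-10 share %.3f, ping-pong z10 %.2f, 1U %.2f, 10A %.2f\n",
                x$pirna$top_share, x$pirna$signature$z10,
                x$pirna$signature$pos1_U_fraction,
                x$pirna$signature$pos10_A_fraction))
  }
  if (!is.null(x$targets)) {
    cat(sprintf("  targets: %d passing sites in %d genes\n",
                sum(x$targets$sites$passed), nrow(x$targets$genes)))
  }
  if (!is.null(x$enrichment)) {
    cat(sprintf("  enrichment: %d significant GO terms, %d significant pathways\n",
                sum(x$enrichment$go$significant),
                sum(x$enrichment$pathway$significant)))
  }
  invisible(x)
}
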
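test_that("precursor windows are excised on both sides and clipped at bounds", {
  set.seed(71)
  g <- c(chr = rand_dna(1000))
  idx <- genome_index(g)
  tag <- substr(g[["chr"]], 401, 422)
  wins <- excise_precursor_windows(tag, map_tag(tag, idx), g)
  expect_equal(nrow(wins), 2L)
  expect_equal(wins$start, c(301L, 381L))
  expect_equal(wins$end, c(442L, 522L))
  expect_true(all(substr(wins$sequence, wins$tag_offset,
                         wins$tag_offset + 21L) == tag))
  # hit at chromosome start: left-clipped, no error
  tag0 <- substr(g[["chr"]], 1, 22)
  wins0 <- excise_precursor_windows(tag0, map_tag(tag0, idx)[1, ], g)
  expect_equal(min(wins0$start), 1L)
})

test_that("hairpin rules use inclusive thresholds on the passing side", {
  set.seed(72)
  mature <- rand_dna(22)
  prec <- paste0(mature, rand_dna(12), revcomp(mature))
  win <- list(sequence = prec, chrom = "c", start = 1L,
              end = nchar(prec), strand = "+", tag_offset = 1L)
  cand <- evaluate_candidate(win, mature, count = 100L)
  expect_true(cand$accepted)
  expect_equal(cand$spacing, 12L)
  expect_equal(cand$max_bulge, 0)
  # count boundary: 44 fails, 45 passes
  expect_false(evaluate_candidate(win, mature, count = 44L)$accepted)
  expect_true(evaluate_candidate(win, mature, count = 45L)$accepted)
  # mature length 17 fails regardless of structure
  m17 <- substr(mature, 1, 17)
  win17 <- list(sequence = prec, tag_offset = 1L)
  expect_false(evaluate_candidate(win17, m17,
                                  count = 100L)$passed_rules[["mature_length"]])
  # energy boundary: -17.5 fails, -18.0 passes (supplied fold)
  f <- fold_rna(prec)
  fake <- function(e) list(structure = f$structure, energy = e)
  expect_false(evaluate_candidate(win, mature, 100L,
                                  fold = fake(-17.5))$passed_rules[["energy"]])
  expect_true(evaluate_candidate(win, mature, 100L,
                                 fold = fake(-18))$passed_rules[["energy"]])
})

test_that("discovery recovers exactly the planted hairpins on the standard fixture", {
  fx <- std_fixture()
  un <- eligible_unannotated(fx$tags, cascade_refs(fx$ref))
  res <- predict_novel_mirnas(un, genome_index(fx$ref$genome), fx$ref$genome)
  rec <- discovery_recovery(res$accepted, fx$ref$truth$planted_mirnas)
  expect_equal(rec$sensitivity, 1)
  expect_equal(rec$false_accepts, 0L)
  # decoy loci are evaluated and fail the energy rule
  dec <- fx$ref$truth$planted_mirnas
  dec <- dec[dec$role == "decoy", ]
  dec_rows <- res$table[res$table$mature %in% dec$mature, ]
  expect_true(nrow(dec_rows) > 0)
  expect_true(all(!dec_rows$rule_energy))
  # heterogeneity table reports 3'-shifted variants for accepted candidates
  het <- res$heterogeneity
  expect_equal(nrow(het), length(res$accepted))
  expect_true(all(het$exact_reads >= 45))
})

test_that("relaxing a threshold never shrinks the accepted set", {
  fx <- std_fixture()
  un <- eligible_unannotated(fx$tags, cascade_refs(fx$ref), min_count = 40L)
  idx <- genome_index(fx$ref$genome)
  strict <- predict_novel_mirnas(un, idx, fx$ref$genome, min_count = 60L)
  relaxed <- predict_novel_mirnas(un, idx, fx$ref$genome, min_count = 45L,
                                  max_energy = -10)
  expect_gte(length(relaxed$accepted), length(strict$accepted))
  key <- function(a) paste(a$chrom, a$mature)
  expect_true(all(vapply(strict$accepted, key, character(1)) %in%
                    vapply(relaxed$accepted, key, character(1))))
})

test_that("empty input and shuffled-genome negative control accept nothing", {
  fx <- std_fixture()
  idx <- genome_index(fx$ref$genome)
  empty <- data.frame(sequence = character(0), count = integer(0))
  expect_length(predict_novel_mirnas(empty, idx, fx$ref$genome)$accepted, 0L)
  # per-chromosome base shuffle destroys the planted loci
  set.seed(73)
  shuf <- vapply(fx$ref$genome, function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, character(1))
  un <- eligible_unannotated(fx$tags, cascade_refs(fx$ref))
  res <- predict_novel_mirnas(un, genome_index(shuf), shuf)
  expect_length(res$accepted, 0L)
})
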
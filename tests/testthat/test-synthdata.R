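test_that("generation is deterministic and byte-identical for a fixed seed", {
  a <- generate_references(7)
  b <- generate_references(7)
  expect_identical(a, b)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synth_fixtures(a, d1, reads = simulate_library(a$truth, seed = 9))
  write_synth_fixtures(b, d2, reads = simulate_library(b$truth, seed = 9))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_false(identical(generate_references(8)$genome, a$genome))
})

test_that("degenerate configs work and capacity overflow raises an error", {
  cfg <- synth_config(n_repeat = 0L, repeat_counts = integer(0),
                      n_line1 = 0L, line1_counts = integer(0),
                      n_ltr = 0L, ltr_counts = integer(0),
                      pirna_target_classes = rep("other", 25L))
  ref <- generate_references(3, cfg)
  expect_length(ref$references$`repeat`, 0)
  expect_false(any(ref$features$class %in%
                     c("repeat", "retrotransposon:LINE1",
                       "retrotransposon:LTR")))
  # cascade still runs with an empty repeat set
  expect_equal(classify_tag(rand_dna(22), cascade_refs(ref)), "unannotated")
  over <- synth_config(chrom_lengths = c(chr1 = 3000L), n_utrs = 30L)
  expect_error(generate_references(3, over), "capacity")
})

test_that("planted matures are genome substrings and truth entries are consistent", {
  cfg <- synth_config(n_known_mirnas = 3L,
                      known_mirna_counts = c(100L, 80L, 60L),
                      n_novel_hairpins = 0L, novel_counts = integer(0),
                      n_decoy_hairpins = 0L, decoy_counts = integer(0))
  ref <- generate_references(11, cfg)
  tm <- ref$truth$planted_mirnas
  expect_equal(nrow(tm), 3L)
  for (i in seq_len(3)) {
    expect_true(grepl(tm$mature[i], ref$genome[[tm$chrom[i]]], fixed = TRUE))
    expect_equal(substr(ref$genome[[tm$chrom[i]]], tm$start[i], tm$end[i]),
                 tm$mature[i])
  }
  # reference catalog sequences are substrings of the genome at their features
  full <- generate_references(12)
  ft <- full$features
  for (k in sample(nrow(ft), 12)) {
    seg <- substr(full$genome[[ft$chrom[k]]], ft$start[k], ft$end[k])
    if (ft$strand[k] == "-") seg <- revcomp(seg)
    if (ft$id[k] %in% names(full$references$`repeat`)) {
      expect_equal(seg, full$references$`repeat`[[ft$id[k]]])
    }
    if (ft$id[k] %in% names(full$references$mRNA)) {
      expect_equal(seg, full$references$mRNA[[ft$id[k]]])
    }
  }
})

test_that("noise-free libraries contain each truth insert verbatim, exactly once", {
  fx <- std_fixture()
  lib <- fx$lib
  tr <- fx$ref$truth
  sources <- c(
    setNames(tr$planted_mirnas$precursor, tr$planted_mirnas$id),
    setNames(tr$planted_pirnas$sequence, tr$planted_pirnas$id),
    setNames(tr$planted_other$sequence, tr$planted_other$id)
  )
  # reads carrying a planted editing event match the edited mature instead
  edited <- setNames(vapply(seq_len(nrow(tr$planted_edits)), function(k) {
    id <- tr$planted_edits$mirna_id[k]
    m <- tr$planted_mirnas$mature[tr$planted_mirnas$id == id]
    substr(m, tr$planted_edits$position[k], tr$planted_edits$position[k]) <-
      tr$planted_edits$alt_base[k]
    m
  }, character(1)), tr$planted_edits$mirna_id)
  set.seed(7)
  for (i in sample(which(!is.na(lib$truth_id)), 200)) {
    id <- lib$truth_id[i]
    ins <- srnapipe:::.strip_adapters_vec(lib$sequence[i],
                                          fx$ref$config$adapter5,
                                          fx$ref$config$adapter3)$insert
    ok <- grepl(ins, sources[[id]], fixed = TRUE) ||
      (id %in% names(edited) && grepl(ins, edited[[id]], fixed = TRUE))
    expect_true(ok, info = id)
  }
  # expected counts equal the number of generated reads per entry
  counts <- table(lib$truth_id)
  for (id in tr$planted_pirnas$id) {
    expect_equal(unname(counts[[id]]),
                 tr$planted_pirnas$expected_count[tr$planted_pirnas$id == id])
  }
  # RawRead invariants: equal lengths, offset-64 scores within [-64, 62]
  expect_true(all(nchar(lib$sequence) == nchar(lib$quality)))
  q <- unlist(decode_quality(unique(lib$quality)))
  expect_true(all(q >= -64 & q <= 62))
})

test_that("multinomial draws stay near expectation and miRNA lengths mode at 22", {
  fx <- std_fixture()
  tr <- fx$ref$truth
  lib <- simulate_library(tr, n_reads = 10000, seed = 13)
  expect_equal(nrow(lib), 10000L)
  counts <- table(lib$truth_id)
  tot <- sum(tr$planted_mirnas$expected_count) +
    sum(tr$planted_pirnas$expected_count) +
    sum(tr$planted_other$expected_count)
  for (id in tr$planted_mirnas$id) {
    p <- tr$planted_mirnas$expected_count[tr$planted_mirnas$id == id] / tot
    expect_lt(abs(counts[[id]] - 10000 * p), 4 * sqrt(10000 * p) + 1)
  }
  # miRNA-class insert length histogram has its mode at 22 nt
  mir_reads <- lib[lib$truth_id %in% tr$planted_mirnas$id, ]
  ins <- clean_reads(mir_reads)$inserts
  expect_equal(as.integer(names(which.max(table(nchar(ins))))), 22L)
  # piRNA-class insert mode in the 26-27 nt band
  pir_reads <- lib[lib$truth_id %in% tr$planted_pirnas$id, ]
  pins <- clean_reads(pir_reads)$inserts
  expect_true(as.integer(names(which.max(table(nchar(pins))))) %in% 26:27)
  expect_error(simulate_library(tr, n_reads = 0, seed = 1), "positive")
  expect_error(simulate_library(tr, error_rate = 0.5, seed = 1), "error_rate")
})

test_that("ping-pong pairs have exact 10-nt 5' overlaps with the configured biases", {
  set.seed(14)
  locus <- rand_dna(200)
  # forced biases: sense starts with T, responder has A at position 10
  pp1 <- simulate_pingpong_reads(locus, n_pairs = 1, seed = 2, bias_1u = 1,
                                 bias_10a = 1)
  sense <- pp1[pp1$role == "primary", ]
  resp <- pp1[pp1$role == "responder", ]
  expect_equal(substr(sense$insert, 1, 1), "T")
  expect_equal(substr(resp$insert, 10, 10), "A")
  expect_equal(resp$end - sense$start + 1L, 10L) # 5'-end overlap
  # realized fractions track the bias parameter
  pp <- simulate_pingpong_reads(locus, n_pairs = 500, seed = 3)
  expect_gte(mean(substr(pp$insert[pp$role == "primary"], 1, 1) == "T"), 0.9)
  expect_gte(mean(substr(pp$insert[pp$role == "responder"], 10, 10) == "A"), 0.9)
  # null construction: first-base T fraction matches the uniform rate
  pp0 <- simulate_pingpong_reads(locus, n_pairs = 1500, seed = 4,
                                 bias_1u = 0.25, bias_10a = 0.25)
  expect_lt(abs(mean(substr(pp0$insert[pp0$role == "primary"], 1, 1) == "T")
                - 0.25), 0.05)
  expect_error(simulate_pingpong_reads(rand_dna(30), 5, 1), "40")
})
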
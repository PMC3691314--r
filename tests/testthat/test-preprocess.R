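ad <- default_adapters()

test_that("offset-64 quality decoding and the Q<10 rule behave as printed", {
  expect_equal(decode_quality("h")[[1]], 40L)  # 104 - 64
  expect_equal(decode_quality("(")[[1]], -24L) # 40 - 64
  expect_false(is_low_quality("ACGT", "hhhh"))
  expect_true(is_low_quality("ACGT", "(((("))
  # threshold boundary: one bad base out of 36
  s <- strrep("A", 36)
  q <- paste0(strrep("h", 35), "E") # E = 69 -> Q = 5
  expect_false(is_low_quality(s, q, max_bad_fraction = 0.5))
  expect_true(is_low_quality(s, q, max_bad_fraction = 0))
  expect_error(is_low_quality("ACGT", "hh"), "length")
})

test_that("adapter stripping recovers inserts and rejects dimers", {
  insert <- "ACGTACGTACGTACGTACGTAC"
  read <- substr(paste0(insert, ad$adapter3), 1, 36)
  res <- strip_adapters(read, ad$adapter5, ad$adapter3)
  expect_equal(res$insert, insert)
  expect_true(is.na(res$reason))
  # 5' adapter fragment is removed first (short insert leaves >= 6 nt of
  # 3' adapter inside the 36-nt read)
  ins18 <- substr(insert, 1, 18)
  read5 <- substr(paste0(substr(ad$adapter5, 17, 26), ins18, ad$adapter3), 1, 36)
  expect_equal(strip_adapters(read5, ad$adapter5, ad$adapter3)$insert, ins18)
  # adapter dimer: nothing left
  dimer <- substr(strrep(ad$adapter3, 2), 1, 36)
  expect_equal(strip_adapters(dimer, ad$adapter5, ad$adapter3)$reason,
               "adapter_dimer")
  # no adapter at all
  res <- strip_adapters(strrep("A", 36), ad$adapter5, ad$adapter3)
  expect_equal(res$reason, "no_3prime_adapter")
})

test_that("adapter stripping is idempotent on recovered inserts", {
  set.seed(11)
  motifs <- srnapipe:::.forbidden_motifs(ad$adapter5, ad$adapter3)
  for (i in 1:20) {
    ins <- srnapipe:::.clean_dna(sample(15:28, 1), motifs)
    once <- strip_adapters(substr(paste0(ins, ad$adapter3), 1, 36),
                           ad$adapter5, ad$adapter3)$insert
    expect_equal(once, ins)
    twice <- strip_adapters(substr(paste0(once, ad$adapter3), 1, 36),
                            ad$adapter5, ad$adapter3)$insert
    expect_equal(twice, once)
  }
})

test_that("clean_reads applies the 11-33 window inclusively and accounts for every read", {
  # untruncated reads so even a 33-nt insert keeps its full 3' adapter
  mk <- function(ins) {
    s <- paste0(ins, ad$adapter3)
    data.frame(sequence = s, quality = strrep("h", nchar(s)),
               stringsAsFactors = FALSE)
  }
  for (len in c(10, 11, 33)) {
    r <- clean_reads(mk(strrep("A", len)))
    if (len == 10) {
      expect_equal(r$summary$rejected_by_reason[["length_window"]], 1L)
    } else {
      expect_equal(r$summary$clean_reads, 1L)
    }
  }
  # 34-nt insert cannot keep a 6-nt adapter inside a 36-nt read: build longer
  r <- clean_reads(data.frame(sequence = paste0(strrep("A", 34), ad$adapter3),
                              quality = strrep("h", 34 + nchar(ad$adapter3))))
  expect_equal(r$summary$rejected_by_reason[["length_window"]], 1L)
  # empty input
  r0 <- clean_reads(data.frame(sequence = character(0), quality = character(0)))
  expect_equal(r0$summary$total_reads, 0L)
  expect_length(r0$inserts, 0L)
})

test_that("read accounting is conserved on a noisy simulated library", {
  ref <- std_fixture()$ref
  lib <- simulate_library(ref$truth, seed = 7, error_rate = 0.01,
                          contamination = 0.05, frac_low_quality = 0.04)
  res <- clean_reads(lib)
  s <- res$summary
  expect_equal(s$total_reads, nrow(lib))
  expect_equal(s$total_reads, s$clean_reads + sum(s$rejected_by_reason))
  tags <- collapse_to_tags(res$inserts)
  expect_equal(sum(tags$count), s$clean_reads)
  expect_true(all(nchar(tags$sequence) >= 11 & nchar(tags$sequence) <= 33))
  expect_true(s$rejected_by_reason[["low_quality"]] > 0)
  expect_true(s$rejected_by_reason[["adapter_dimer"]] > 0)
  expect_true(s$rejected_by_reason[["contains_N"]] > 0)
})

test_that("tag collapsing counts, sorts and breaks ties deterministically", {
  tags <- collapse_to_tags(c("AAC", "AAC", "GGT"))
  expect_equal(tags$sequence, c("AAC", "GGT"))
  expect_equal(tags$count, c(2L, 1L))
  # all distinct: n tags of count 1, lexicographic order
  tags <- collapse_to_tags(c("TTT", "AAA", "CCC"))
  expect_equal(tags$sequence, c("AAA", "CCC", "TTT"))
  expect_equal(tags$count, rep(1L, 3))
  expect_equal(nrow(collapse_to_tags(character(0))), 0L)
})
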
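test_that("piRNA catalog matching reports the most abundant tag per entry", {
  set.seed(81)
  cat31 <- rand_dna(31)
  catalog <- c(piA = cat31, piB = rand_dna(26))
  tags <- data.frame(
    sequence = c(cat31, substr(cat31, 2, 31), catalog[["piB"]], rand_dna(25)),
    count = c(100L, 300L, 50L, 10L)
  )
  hits <- match_pirna_catalog(tags, catalog)
  expect_equal(hits$pirna, c("piA", "piB")) # sorted by total count
  a <- hits[hits$pirna == "piA", ]
  expect_equal(a$total_count, 400)
  # the 30-nt suffix tag outnumbers the full-length one
  expect_equal(a$top_tag, substr(cat31, 2, 31))
  expect_equal(a$top_tag_length, 30L)
  expect_equal(a$top_tag_count, 300)
  expect_true(a$top_tag_count <= a$total_count)
  # unmatched tags appear nowhere
  expect_false(any(grepl(tags$sequence[4], hits$top_tag, fixed = TRUE)))
  # RNA-alphabet catalogs match T-space tags
  hits_u <- match_pirna_catalog(tags, chartr("T", "U", catalog))
  expect_equal(hits_u$total_count, hits$total_count)
})

test_that("positional base bias is count-weighted and sums to one", {
  tags <- data.frame(sequence = c("TAAA", "TCCC", "GAAA"),
                     count = c(3L, 1L, 4L))
  b <- positional_base_bias(tags, 1)
  expect_equal(sum(b), 1)
  expect_equal(b[["T"]], 0.5)
  expect_equal(b[["G"]], 0.5)
  expect_error(positional_base_bias(tags, 5), "position")
  # uniform random tags: each base around 0.25
  set.seed(82)
  tags <- data.frame(sequence = vapply(1:2000, function(i) rand_dna(20),
                                       character(1)), count = 1L)
  b <- positional_base_bias(tags, 10)
  expect_true(all(abs(b - 0.25) < 0.05))
})

test_that("a constructed opposite-strand pair lands in the 10-nt overlap bin", {
  reads <- data.frame(
    chrom = "c", start = c(100L, 91L), end = c(127L, 109L),
    strand = c("+", "-"),
    sequence = c(strrep("T", 28), paste0(strrep("G", 9), "A", strrep("G", 9))),
    count = 1L
  )
  sig <- pingpong_overlap_signature(reads)
  expect_equal(unname(sig$overlap_histogram[["10"]]), 1L)
  expect_equal(sig$n_pairs, 1L)
  expect_equal(sum(sig$overlap_histogram), sig$n_pairs)
  expect_equal(sig$pos1_U_fraction, 1)
  expect_equal(sig$pos10_A_fraction, 1)
  # no opposite-strand pairs: all-zero histogram, z10 missing
  sig0 <- pingpong_overlap_signature(reads[1, ])
  expect_equal(sum(sig0$overlap_histogram), 0L)
  expect_true(is.na(sig0$z10))
})

test_that("simulated ping-pong libraries peak at 10 nt; shuffled nulls do not", {
  set.seed(83)
  locus <- rand_dna(160)
  pp <- simulate_pingpong_reads(locus, n_pairs = 300, seed = 84)
  reads <- pp[, c("chrom", "start", "end", "strand")]
  reads$sequence <- pp$insert
  sig <- pingpong_overlap_signature(reads)
  expect_equal(which.max(sig$overlap_histogram), c("10" = 10L))
  expect_gt(sig$z10, 3)
  # position-shuffled null
  null_z <- replicate(25, {
    r <- reads
    w <- nchar(r$sequence)
    r$start <- sample(140L, nrow(r), replace = TRUE)
    r$end <- r$start + w - 1L
    pingpong_overlap_signature(r)$z10
  })
  expect_true(mean(null_z < 2, na.rm = TRUE) >= 0.9)
})

test_that("top_share computes abundance concentration", {
  expect_equal(top_share(c(50, 30, 20), 2), 0.8)
  expect_equal(top_share(10, 1), 1)
  expect_equal(top_share(data.frame(total_count = c(61, 39)), 1), 0.61)
  expect_error(top_share(numeric(0), 1), "empty")
})

test_that("piRNA target classes follow the best antisense alignment", {
  set.seed(85)
  line1 <- rand_dna(200)
  utr <- rand_dna(150)
  pirnas <- c(revcomp(substr(line1, 50, 77)), revcomp(substr(utr, 10, 36)),
              rand_dna(28))
  res <- classify_pirna_targets(
    pirnas, c(L1 = line1, G1 = utr),
    c("retrotransposon:LINE1", "mRNA")
  )
  expect_equal(res$assignments$class,
               c("retrotransposon:LINE1", "mRNA", "unassigned"))
  expect_equal(sum(res$fractions), 1)
  expect_false("unassigned" %in% names(res$fractions))
})
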
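test_that("map_tag finds exact and 1-mismatch hits but not 2-mismatch ones", {
  set.seed(61)
  g <- c(chrA = rand_dna(3000), chrB = rand_dna(2000))
  idx <- genome_index(g)
  tag <- substr(g[["chrA"]], 501, 522)
  h <- map_tag(tag, idx)
  expect_true(any(h$chrom == "chrA" & h$start == 501 & h$mismatches == 0))
  v <- strsplit(tag, "")[[1]]
  v[10] <- setdiff(c("A", "C", "G", "T"), v[10])[1]
  h1 <- map_tag(paste(v, collapse = ""), idx)
  expect_true(any(h1$chrom == "chrA" & h1$start == 501 & h1$mismatches == 1))
  v[15] <- setdiff(c("A", "C", "G", "T"), v[15])[1]
  h2 <- map_tag(paste(v, collapse = ""), idx)
  expect_false(any(h2$chrom == "chrA" & h2$start == 501))
  # N-containing tags map nowhere
  expect_equal(nrow(map_tag(paste0(substr(tag, 1, 21), "N"), idx)), 0L)
  # minus strand: reverse complement of a genomic substring
  rtag <- revcomp(substr(g[["chrB"]], 301, 326))
  hm <- map_tag(rtag, idx)
  expect_true(any(hm$chrom == "chrB" & hm$start == 301 & hm$strand == "-" &
                    hm$mismatches == 0))
})

test_that("map_tag equals the brute-force scan on a random genome", {
  set.seed(62)
  g <- c(c1 = rand_dna(8000), c2 = rand_dna(4000))
  idx <- genome_index(g)
  for (i in 1:30) {
    if (i %% 3 == 0) {
      tag <- rand_dna(sample(13:28, 1)) # mostly non-matching
    } else {
      ch <- sample(names(g), 1)
      L <- sample(15:28, 1)
      st <- sample(nchar(g[[ch]]) - L, 1)
      tag <- substr(g[[ch]], st, st + L - 1)
      v <- strsplit(tag, "")[[1]]
      p <- sample(L, 1)
      v[p] <- sample(c("A", "C", "G", "T"), 1)
      tag <- paste(v, collapse = "")
      if (i %% 2 == 0) tag <- revcomp(tag)
    }
    expect_equal(map_tag(tag, idx), oracle_map_bruteforce(tag, g), info = tag)
  }
})

test_that("the cascade assigns the highest-priority matching category", {
  set.seed(63)
  mir <- rand_dna(22)
  rep1 <- paste0(rand_dna(50), mir, rand_dna(50)) # repeat containing the miRNA
  pir <- rand_dna(28)
  refs <- list(miRNA = c(m1 = mir), piRNA = c(p1 = pir),
               `repeat` = c(r1 = rep1))
  expect_equal(classify_tag(mir, refs), "miRNA")   # not repeat
  expect_equal(classify_tag(pir, refs), "piRNA")
  expect_equal(classify_tag(rand_dna(25), refs), "unannotated")
  # load order of the reference list never changes the category
  expect_equal(classify_tag(mir, rev(refs)), "miRNA")
  # one mismatch still matches
  v <- strsplit(pir, "")[[1]]; v[5] <- setdiff(c("A","C","G","T"), v[5])[1]
  expect_equal(classify_tag(paste(v, collapse = ""), refs), "piRNA")
})

test_that("category summary conserves tags, reads and percentages", {
  fx <- std_fixture()
  idx <- genome_index(fx$ref$genome)
  rec <- annotate_tags(fx$tags, idx, cascade_refs(fx$ref))
  cs <- summarize_categories(rec)
  tot <- cs[cs$category == "Total", ]
  expect_equal(tot$unique_tags, nrow(fx$tags))
  expect_equal(tot$total_reads, sum(fx$tags$count))
  body <- cs[cs$category != "Total", ]
  expect_equal(sum(body$unique_tags_percent), 100, tolerance = 1e-8)
  expect_equal(sum(body$total_reads_percent), 100, tolerance = 1e-8)
  expect_equal(sum(body$unique_tags), tot$unique_tags)
  # planted 3x more miRNA than piRNA reads: shares must rank accordingly
  expect_gt(body$total_reads[body$category == "miRNA"],
            body$total_reads[body$category == "piRNA"])
  # chromosome distribution conserves mapped reads (fractional multi-hits)
  cd <- chromosome_distribution(rec)
  expect_equal(sum(cd), sum(rec$count[rec$n_hits > 0]))
})

test_that("fractional chromosome assignment splits multi-hit counts", {
  g <- c(cA = paste0(rand_dna(100), "ACGTACGTACGTACGTACGTAA", rand_dna(100)),
         cB = paste0(rand_dna(50), "ACGTACGTACGTACGTACGTAA", rand_dna(150)))
  idx <- genome_index(g)
  tags <- data.frame(sequence = "ACGTACGTACGTACGTACGTAA", count = 4L)
  rec <- annotate_tags(tags, idx, list())
  cd <- chromosome_distribution(rec)
  expect_equal(sum(cd), 4)
  expect_equal(unname(cd["cA"]), unname(cd["cB"]))
})

test_that("known-miRNA quantification recovers planted rank order", {
  set.seed(64)
  cat <- c(hi = rand_dna(22), mid = rand_dna(22), lo = rand_dna(22))
  tags <- data.frame(sequence = unname(cat), count = c(1000L, 100L, 10L))
  rec <- data.frame(sequence = tags$sequence, count = tags$count,
                    category = "miRNA", n_hits = 1L)
  tab <- quantify_known_mirnas(rec, cat)
  expect_equal(tab$mirna, c("hi", "mid", "lo"))
  expect_equal(tab$reads, c(1000, 100, 10))
  expect_lte(nrow(top_n_expressed(tab, 10)), 10)
  expect_equal(top_n_expressed(tab, 2)$mirna, c("hi", "mid"))
  # undetected catalog entries are absent
  tab2 <- quantify_known_mirnas(rec[1, , drop = FALSE], cat)
  expect_false("lo" %in% tab2$mirna)
})

test_that("editing detection applies the >10% rule on pooled reads", {
  set.seed(65)
  mir <- c(m1 = rand_dna(22))
  edited <- strsplit(mir[[1]], "")[[1]]
  edited[10] <- setdiff(c("A", "C", "G", "T"), edited[10])[1]
  edited <- paste(edited, collapse = "")
  mk <- function(counts) data.frame(
    sequence = c(mir[[1]], edited), count = counts,
    category = "miRNA", n_hits = 1L, stringsAsFactors = FALSE)
  hit <- detect_editing(mk(c(85L, 15L)), mir)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$position, 10L)
  expect_equal(hit$edited_fraction, 0.15)
  expect_equal(nrow(detect_editing(mk(c(95L, 5L)), mir)), 0L)
  none <- data.frame(sequence = mir[[1]], count = 100L, category = "miRNA",
                     n_hits = 1L)
  expect_equal(nrow(detect_editing(none, mir)), 0L)
  # positions within 2 nt of either end are ignored (end heterogeneity)
  edited2 <- strsplit(mir[[1]], "")[[1]]
  edited2[2] <- setdiff(c("A", "C", "G", "T"), edited2[2])[1]
  mk2 <- data.frame(sequence = c(mir[[1]], paste(edited2, collapse = "")),
                    count = c(50L, 50L), category = "miRNA", n_hits = 1L)
  expect_equal(nrow(detect_editing(mk2, mir)), 0L)
})
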
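test_that("E-ratio is the fold enrichment (m/M)/(n/N)", {
  expect_equal(e_ratio(2, 10, 4, 100), 5)
  expect_equal(e_ratio(3, 30, 10, 100), 1)  # m/M == n/N
  expect_equal(e_ratio(0, 10, 4, 100), 0)
  expect_error(e_ratio(1, 0, 4, 100), "positive")
})

test_that("hypergeometric tail matches enumeration over all draws at tiny N", {
  # N=10, n=3, M=5, m=3: direct enumeration over all C(10,5) draws
  draws <- utils::combn(10, 5)
  annotated <- 1:3
  frac <- mean(apply(draws, 2, function(d) sum(d %in% annotated) >= 3))
  expect_equal(frac, 1 / 12)
  expect_equal(hypergeometric_tail_p(3, 5, 3, 10), frac, tolerance = 1e-12)
  expect_equal(hypergeometric_tail_p(0, 5, 3, 10), 1)
})

test_that("tail p agrees with the summation oracle and behaves monotonically", {
  set.seed(101)
  for (i in 1:200) {
    N <- sample(5:60, 1); n <- sample(N, 1); M <- sample(N, 1)
    supp <- max(0, n + M - N):min(n, M)
    m <- supp[sample.int(length(supp), 1)]
    expect_equal(hypergeometric_tail_p(m, M, n, N),
                 oracle_hyper_tail(m, M, n, N), tolerance = 1e-9,
                 info = paste(m, M, n, N))
  }
  # PMF normalization and tail monotonicity at fixed margins
  for (i in 1:20) {
    N <- sample(10:60, 1); n <- sample(N, 1); M <- sample(N, 1)
    ms <- max(0, n + M - N):min(n, M)
    pmf <- vapply(ms, function(m) {
      exp(lchoose(n, m) + lchoose(N - n, M - m) - lchoose(N, M))
    }, numeric(1))
    expect_equal(sum(pmf), 1, tolerance = 1e-9)
    tails <- vapply(ms, hypergeometric_tail_p, numeric(1), M = M, n = n, N = N)
    expect_true(all(diff(tails) <= 1e-12))
  }
})

test_that("one-sided Fisher equals the hypergeometric tail", {
  set.seed(102)
  for (i in 1:100) {
    N <- sample(5:60, 1); n <- sample(N, 1); M <- sample(N, 1)
    supp <- max(0, n + M - N):min(n, M)
    m <- supp[sample.int(length(supp), 1)]
    expect_equal(fisher_exact_p(m, M, n, N),
                 hypergeometric_tail_p(m, M, n, N), tolerance = 1e-9)
  }
  # the extreme table gives the smallest attainable p at fixed margins
  N <- 40; n <- 12; M <- 15
  ps <- vapply(max(0, n + M - N):min(n, M), fisher_exact_p, numeric(1),
               M = M, n = n, N = N)
  expect_equal(which.min(ps), length(ps))
  expect_equal(fisher_exact_p(0, M, n, N), 1)
  expect_error(fisher_exact_p(0, 12, 10, 15), "cell|exceed")
})

test_that("enrich applies strict thresholds and deterministic ordering", {
  universe <- sprintf("g%03d", 1:1000)
  targets <- universe[1:100]
  # planted 5-fold enriched term: m=10 of M=100, n=20 of N=1000
  map <- rbind(
    data.frame(gene = universe, term = "T:base"),
    data.frame(gene = c(targets[1:10], universe[901:910]), term = "T:enr")
  )
  res <- enrich(map, targets, universe, min_e_ratio = 2, max_p = 0.05)
  enr <- res[res$term == "T:enr", ]
  expect_equal(enr$e_ratio, 5)
  expect_equal(enr$p_value, oracle_hyper_tail(10, 100, 20, 1000),
               tolerance = 1e-9)
  expect_true(enr$significant)
  # a term carried by every gene is never enriched
  base <- res[res$term == "T:base", ]
  expect_equal(base$e_ratio, 1)
  expect_false(base$significant)
  # ordering: e_ratio descending
  expect_equal(res$term, c("T:enr", "T:base"))
  # pathway-style threshold pair on the same inputs
  res_pw <- enrich(map, targets, universe, min_e_ratio = 1.5, max_p = 0.05,
                   test = "fisher")
  expect_equal(res_pw$p_value, res$p_value, tolerance = 1e-9)
  expect_error(enrich(map, targets, character(0)), "empty")
  expect_error(enrich(map, c(targets, "not_there"), universe), "subset")
})
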
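test_that("descriptive statistics are exact and order-invariant", {
  traits <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1,
                   dimnames = list(paste0("s", 1:6), "x"))
  ch <- bin_char(c(0, 0, 0, 1, 1, 1), paste0("s", 1:6))
  d <- descriptive_stats(traits, ch)
  expect_equal(d$mean, c(2, 5))
  expect_equal(d$sd, c(1, 1))
  d2 <- descriptive_stats(traits[sample(6), , drop = FALSE], ch)
  expect_equal(d2$mean, d$mean)
  # degenerate group: single species, SD reported as 0 with a warning
  ch1 <- bin_char(c(0, 1, 1, 1, 1, 1), paste0("s", 1:6))
  expect_warning(d3 <- descriptive_stats(traits, ch1), "single species")
  expect_equal(d3$sd[1], 0)
})

test_that("Holm adjustment matches the direct step-down formula", {
  expect_equal(holm_adjust(c(.01, .04, .03)), c(.03, .06, .06))
  expect_equal(holm_adjust(0.2), 0.2)                 # m = 1: identity
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  # direct formula on random vectors: sort, multiply, running max, cap
  set.seed(40)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    o <- order(p)
    m <- length(p)
    adj <- pmin(cummax(p[o] * (m - seq_len(m) + 1)), 1)
    direct <- numeric(m); direct[o] <- adj
    expect_equal(holm_adjust(p), direct)
  }
  # monotone and idempotent-safe
  p <- c(0.02, 0.5, 0.04)
  a1 <- holm_adjust(p)
  expect_true(all(a1 >= p))
  expect_true(all(holm_adjust(a1) >= a1))
  expect_error(holm_adjust(c(0.5, 0)), "0, 1")
})

test_that("phylogenetic t-test recovers an obvious shift on a star tree", {
  star <- parse_newick(paste0("(", paste0("s", 1:12, ":1", collapse = ","),
                              ");"))
  ch <- bin_char(rep(c(0, 1), each = 6), paste0("s", 1:12))
  x <- setNames(c(rnorm(6, 0, 0.05), rnorm(6, 100, 0.05)), paste0("s", 1:12))
  r <- phylo_ttest(star, x, ch, n_sims = 500, seed = 41)
  expect_lte(r$p, 0.01)
  expect_equal(r$mean, c(mean(x[1:6]), mean(x[7:12])))
  # constant trait: p = 1 with a warning
  xc <- setNames(rep(1, 12), paste0("s", 1:12))
  expect_warning(rc <- phylo_ttest(star, xc, ch, n_sims = 200), "constant")
  expect_equal(rc$p, 1)
})

test_that("phylogeny-tracking groups are discounted relative to plain t", {
  # labels perfectly tracking a deep two-clade split under BM: the
  # phylogenetic p must typically exceed the naive t-test p
  tr <- parse_newick(paste0(
    "((", paste0("a", 1:6, ":1", collapse = ","), "):9,",
    "(", paste0("b", 1:6, ":1", collapse = ","), "):9);"))
  ch <- bin_char(rep(c(0, 1), each = 6), tr$tip.label)
  set.seed(42)
  wins <- 0
  for (i in 1:40) {
    x <- simulate_bm(tr, sigma2 = 1, n = 1, internal = FALSE)
    r <- phylo_ttest(tr, x, ch, n_sims = 299)
    t_naive <- t.test(x[7:12], x[1:6], var.equal = TRUE)$p.value
    if (r$p > t_naive) wins <- wins + 1
  }
  expect_gt(wins / 40, 0.7)
})

test_that("the t-test table applies Holm across traits", {
  tr <- make_yule_tree(14, seed = 43)
  X <- simulate_bm(tr, sigma2 = c(1, 1, 1), n = 1, internal = FALSE)
  colnames(X) <- c("u", "v", "w")
  ch <- bin_char(rep(c(0, 1), 7), tr$tip.label)
  tab <- phylo_ttest_table(tr, X, ch, n_sims = 199, seed = 44)
  expect_equal(tab$p_holm, holm_adjust(tab$p))
  expect_true(all(tab$p_holm >= tab$p))
})

test_that("Pagel likelihood matches brute-force state enumeration", {
  skip_if_not_installed("Matrix")
  set.seed(45)
  for (ntip in c(4, 6)) {
    tr <- make_yule_tree(ntip, seed = ntip + 50)
    pair <- sim_char_pair(tr)
    for (i in 1:3) {
      r8 <- exp(runif(8, -2, 1))
      ll <- pagel_loglik(tr, pair$a, pair$b, r8)
      bf <- brute_pagel_loglik(tr, pair$a, pair$b, r8)
      expect_equal(ll, bf, tolerance = 1e-8)
    }
    # independent model: 4 rates expanded to 8
    r4 <- exp(runif(4, -2, 1))
    expect_equal(pagel_loglik(tr, pair$a, pair$b, r4),
                 brute_pagel_loglik(tr, pair$a, pair$b,
                                    r4[c(1, 1, 2, 2, 3, 3, 4, 4)]),
                 tolerance = 1e-8)
  }
})

test_that("Pagel test: LR is non-negative and constant characters error", {
  tr <- make_yule_tree(15, seed = 60)
  pair <- sim_char_pair(tr)
  r <- pagel_correlation(tr, pair$a, pair$b, n_sims = 0, seed = 61)
  expect_gte(r$LR, 0)
  expect_gte(r$ll_dep, r$ll_indep)
  const <- setNames(rep(1L, 15), tr$tip.label)
  expect_error(pagel_correlation(tr, const, pair$b, n_sims = 0),
               "constant")
})

test_that("Pagel test detects a duplicated character", {
  set.seed(62)
  tr <- make_yule_tree(30, seed = 63)
  hits <- 0
  for (i in 1:6) {
    pair <- sim_char_pair(tr, q = 0.6)
    r <- pagel_correlation(tr, pair$a, pair$a, n_sims = 99,
                           seed = 64 + i, n_starts = 1, maxit = 150)
    if (r$p <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 5)
})
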
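test_that("BM simulation honours degenerate and analytic cases", {
  tr <- balanced4()
  # sigma2 = 0: every node equals the root state
  x <- simulate_bm(tr, sigma2 = 0, root_state = 3.5, seed = 1)
  expect_equal(unname(x), rep(3.5, 7))

  # single branch of length 3, rate 2: tip variance 6 within 3 MC SEs
  t1 <- parse_newick("(A:3,B:1e-8);")
  y <- simulate_bm(t1, sigma2 = 2, n = 10000, internal = FALSE, seed = 2)
  v <- var(y["A", ])
  se <- 6 * sqrt(2 / 9999)       # SE of a variance estimate for N(0, 6)
  expect_lt(abs(v - 6), 3 * se)

  # sister tips: covariance ~ sigma2 x shared path length
  t2 <- parse_newick("((A:1,B:1):1,C:2);")
  y2 <- simulate_bm(t2, sigma2 = 1, n = 20000, internal = FALSE, seed = 3)
  expect_lt(abs(cov(y2["A", ], y2["B", ]) - 1), 0.06)
  expect_lt(abs(cov(y2["A", ], y2["C", ])), 0.06)
})

test_that("multivariate BM respects the evolutionary covariance", {
  tr <- balanced4()
  R <- matrix(c(1, 0.8, 0.8, 1), 2)
  X <- simulate_bm(tr, R = R, n = 8000, internal = FALSE, seed = 4)
  # trait-trait covariance at one tip accumulates R * depth (depth = 2)
  cc <- cov(X[1, 1, ], X[1, 2, ])
  expect_lt(abs(cc - 1.6), 0.12)
})

test_that("GLS rate estimation matches the brute-force matrix formula", {
  set.seed(5)
  tr <- ape::rtree(6)
  x <- setNames(rnorm(6), tr$tip.label)
  C <- phylo_vcv(tr)
  Ci <- solve(C)
  mu <- sum(Ci %*% x) / sum(Ci)
  s2 <- drop(t(x - mu) %*% Ci %*% (x - mu)) / (6 - 1)
  fit <- estimate_bm_rate(tr, x)
  expect_equal(unname(fit$sigma2), s2, tolerance = 1e-10)
  # equals the independent-contrasts REML estimator on a binary tree
  expect_equal(unname(fit$sigma2), sum(ape::pic(x, tr)^2) / 5,
               tolerance = 1e-10)
  # constant tip values -> rate 0
  expect_equal(unname(estimate_bm_rate(tr, setNames(rep(2, 6),
                                                    tr$tip.label))$sigma2),
               0, tolerance = 1e-12)
  # invariant to tip ordering
  fit2 <- estimate_bm_rate(tr, x[sample(names(x))])
  expect_equal(fit$sigma2, fit2$sigma2)
})

test_that("rate estimation recovers the simulating rate", {
  tr <- make_yule_tree(200, seed = 6)
  x <- simulate_bm(tr, sigma2 = 1, n = 1, internal = FALSE, seed = 7)
  est <- estimate_bm_rate(tr, x)$sigma2
  expect_gt(est, 0.8); expect_lt(est, 1.2)

  # near-unbiasedness over replicates on a 100-tip tree
  tr2 <- make_yule_tree(100, seed = 8)
  Y <- simulate_bm(tr2, sigma2 = 2, n = 200, internal = FALSE, seed = 9)
  ests <- apply(Y, 2, function(y)
    estimate_bm_rate(tr2, setNames(y, tr2$tip.label))$sigma2)
  expect_lt(abs(mean(ests) - 2) / 2, 0.05)
})

test_that("ML ancestral states solve the symmetric cases exactly", {
  t2 <- parse_newick("(A:1,B:1);")
  a <- ancestral_ml(t2, c(A = 0, B = 4))
  expect_equal(unname(a["3", 1]), 2)

  star <- parse_newick("(A:1,B:1,C:1,D:1);")
  vals <- c(A = 1, B = 2, C = 3, D = 10)
  expect_equal(unname(ancestral_ml(star, vals)["5", 1]), mean(vals))
})

test_that("ML ancestral states equal the GLS conditional mean oracle", {
  set.seed(10)
  tr <- ape::rtree(8)
  x <- setNames(rnorm(8), tr$tip.label)
  est <- ancestral_ml(tr, x)
  # oracle: conditional multivariate-normal mean with GLS root, built from
  # first principles via node depths and MRCAs
  ntot <- 8 + tr$Nnode
  depth <- ape::node.depth.edgelength(tr)
  M <- ape::mrca(tr, full = TRUE)
  Cfull <- matrix(depth[M], ntot, ntot)
  C <- Cfull[1:8, 1:8]
  Ci <- solve(C)
  mu <- sum(Ci %*% x[tr$tip.label]) / sum(Ci)
  for (nd in (8 + 1):ntot) {
    cav <- Cfull[nd, 1:8]
    oracle <- mu + drop(cav %*% Ci %*% (x[tr$tip.label] - mu))
    expect_equal(unname(est[as.character(nd), 1]), oracle, tolerance = 1e-9)
  }
  # tips are constraints, not estimates
  expect_equal(est[tr$tip.label, 1], x[tr$tip.label])
})

test_that("ML ancestral states agree with an independent implementation", {
  skip_if_not_installed("phytools")
  set.seed(11)
  tr <- ape::rtree(12)
  x <- setNames(rnorm(12), tr$tip.label)
  mine <- ancestral_ml(tr, x)
  ref <- phytools::fastAnc(tr, x)
  expect_equal(unname(mine[names(ref), 1]), unname(as.numeric(ref)),
               tolerance = 1e-8)
})

test_that("ancestral estimation is linear in the tip values", {
  set.seed(12)
  tr <- make_yule_tree(10, seed = 13)
  y1 <- setNames(rnorm(10), tr$tip.label)
  y2 <- setNames(rnorm(10), tr$tip.label)
  a <- 2.5; b <- -1.25
  lhs <- ancestral_ml(tr, a * y1 + b * y2)
  rhs <- a * ancestral_ml(tr, y1) + b * ancestral_ml(tr, y2)
  expect_equal(unname(lhs), unname(rhs), tolerance = 1e-10)
})

test_that("OU simulation has the exact edge mean and variance", {
  alpha <- 1.2; s2 <- 0.8; th <- 5; t_len <- 2
  t1 <- parse_newick(sprintf("(A:%g,B:1e-8);", t_len))
  y <- simulate_ou(t1, alpha = alpha, theta = rep(th, 1), sigma2 = s2,
                   root_state = 0, n = 10000, internal = FALSE, seed = 14)
  m_exp <- th + (0 - th) * exp(-alpha * t_len)
  v_exp <- s2 * (1 - exp(-2 * alpha * t_len)) / (2 * alpha)
  expect_lt(abs(mean(y["A", ]) - m_exp), 4 * sqrt(v_exp / 10000))
  expect_lt(abs(var(y["A", ]) - v_exp) / v_exp, 0.06)

  # alpha*t large: the tip forgets the root and sits at its regime optimum
  t3 <- parse_newick("(A:10,B:1e-8);")
  y3 <- simulate_ou(t3, alpha = 1, theta = rep(th, 1), sigma2 = s2,
                    root_state = -20, n = 4000, internal = FALSE, seed = 15)
  expect_lt(abs(mean(y3["A", ]) - th), 4 * sqrt(s2 / 2 / 4000) + 0.01)
})

test_that("OU with alpha = 0 is distributed as Brownian motion", {
  tr <- balanced4()
  a <- simulate_ou(tr, alpha = 0, theta = rep(0, 1), sigma2 = 1,
                   n = 5000, internal = FALSE, seed = 16)
  b <- simulate_bm(tr, sigma2 = 1, n = 5000, internal = FALSE, seed = 17)
  for (tip in c("A", "C")) {
    ks <- suppressWarnings(stats::ks.test(a[tip, ], b[tip, ]))
    expect_gt(ks$p.value, 0.01)
  }
})
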
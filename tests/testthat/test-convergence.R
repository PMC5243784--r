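test_that("Stayton indices match the exhaustive hand-worked instance", {
  tr <- parse_newick("((F1:1,X1:1):1,(F2:1,X2:1):1);")
  traits <- matrix(c(0, 5, 1, 7), 4, 1,
                   dimnames = list(c("F1", "X1", "F2", "X2"), "z"))
  # supplied ancestors: F1's parent -2, F2's parent 3, root 0
  anc <- rbind(traits, matrix(c(0, -2, 3), 3, 1,
                              dimnames = list(c("5", "6", "7"), "z")))
  s <- stayton_indices(tr, traits, c("F1", "F2"), anc = anc)
  expect_equal(s$pairs$Dmax, 5)   # |-2 - 3|, an ancestor-ancestor pair
  expect_equal(s$pairs$Dtip, 1)
  expect_equal(s$C1, 0.8)
  expect_equal(s$C2, 4)
})

test_that("Stayton indices hit their boundary cases", {
  tr <- parse_newick("((F1:1,X1:1):1,(F2:1,X2:1):1);")
  traits <- matrix(c(2, 9, 2, -4), 4, 1,
                   dimnames = list(c("F1", "X1", "F2", "X2"), "z"))
  # identical focal tips: complete convergence, C1 = 1
  s <- stayton_indices(tr, traits, c("F1", "F2"))
  expect_equal(s$C1, 1)
  # monotonically diverging trajectory: Dtip is the maximum, C1 = C2 = 0
  anc <- rbind(traits, matrix(c(0, 0.5, -0.5), 3, 1,
                              dimnames = list(c("5", "6", "7"), "z")))
  traits2 <- traits; traits2["F1", ] <- 3; traits2["F2", ] <- -3
  s2 <- stayton_indices(tr, traits2, c("F1", "F2"), anc = rbind(
    traits2, matrix(c(0, 0.5, -0.5), 3, 1,
                    dimnames = list(c("5", "6", "7"), "z"))))
  expect_equal(s2$C1, 0)
  expect_equal(s2$C2, 0)
})

test_that("Stayton indices equal an exhaustive node-pair enumeration", {
  set.seed(20)
  tr <- make_yule_tree(8, seed = 21)
  X <- simulate_bm(tr, sigma2 = c(1, 1), n = 1, internal = FALSE)
  colnames(X) <- c("u", "v")
  anc <- ancestral_ml(tr, X)
  focal <- tr$tip.label[c(1, 4, 6)]
  s <- stayton_indices(tr, X, focal, anc = anc)
  # oracle: walk root-paths by explicit parent pointers, enumerate all pairs
  parent <- integer(8 + tr$Nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])
  M <- ape::mrca(tr)
  fid <- match(focal, tr$tip.label)
  cmb <- combn(3, 2)
  for (k in seq_len(ncol(cmb))) {
    i <- fid[cmb[1, k]]; j <- fid[cmb[2, k]]
    m <- M[i, j]
    pa <- i; while (pa[length(pa)] != m) pa <- c(pa, parent[pa[length(pa)]])
    pb <- j; while (pb[length(pb)] != m) pb <- c(pb, parent[pb[length(pb)]])
    dmax <- 0
    for (a in pa) for (b in pb) {
      dmax <- max(dmax, sqrt(sum((anc[a, ] - anc[b, ])^2)))
    }
    dtip <- sqrt(sum((anc[i, ] - anc[j, ])^2))
    row <- which(s$pairs$tip1 == tr$tip.label[i] &
                   s$pairs$tip2 == tr$tip.label[j])
    expect_equal(s$pairs$Dmax[row], dmax, tolerance = 1e-12)
    expect_equal(s$pairs$C1[row], 1 - dtip / dmax, tolerance = 1e-12)
  }
  # C3/C4 denominators: summed Euclidean steps along lineages / whole tree
  step <- sqrt(rowSums((anc[tr$edge[, 1], ] - anc[tr$edge[, 2], ])^2))
  expect_equal(s$C4, mean(s$pairs$C2 / sum(step)), tolerance = 1e-12)
})

test_that("C1 is invariant under rigid rotation of trait space", {
  set.seed(22)
  tr <- make_yule_tree(10, seed = 23)
  X <- simulate_bm(tr, sigma2 = c(1, 1), n = 1, internal = FALSE)
  colnames(X) <- c("u", "v")
  focal <- tr$tip.label[1:4]
  th <- 0.7
  Rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  XR <- X %*% Rot + 3   # rotation plus translation
  colnames(XR) <- c("u", "v")
  s1 <- stayton_indices(tr, X, focal)
  s2 <- stayton_indices(tr, XR, focal)
  expect_equal(s1$C1, s2$C1, tolerance = 1e-10)
  expect_equal(s1$C2, s2$C2, tolerance = 1e-10)
  # uniform rescaling: C2 scales linearly, C1/C3/C4 are invariant
  s3 <- stayton_indices(tr, X * 4, focal)
  expect_equal(s3$C1, s1$C1, tolerance = 1e-10)
  expect_equal(s3$C2, 4 * s1$C2, tolerance = 1e-10)
  expect_equal(s3$C3, s1$C3, tolerance = 1e-10)
  expect_equal(s3$C4, s1$C4, tolerance = 1e-10)
})

test_that("simulation p-values carry +1 smoothing and the focal contract", {
  set.seed(24)
  tr <- make_yule_tree(12, seed = 25)
  X <- simulate_bm(tr, sigma2 = c(1, 1), n = 1, internal = FALSE)
  colnames(X) <- c("u", "v")
  s <- stayton_significance(tr, X, tr$tip.label[1:4], n_sims = 100,
                            seed = 26)
  expect_true(all(s$p > 0 & s$p <= 1))
  expect_equal(nrow(s$sim), 100)
  expect_error(stayton_significance(tr, X, tr$tip.label[1:4], n_sims = 50),
               ">= 100")
})

test_that("Wheatsheaf index: direction, identity, and matrix oracle", {
  set.seed(27)
  tr <- make_yule_tree(6, seed = 28)
  X <- simulate_bm(tr, sigma2 = c(1, 1), n = 1, internal = FALSE)
  colnames(X) <- c("u", "v")
  # focal set = all taxa: w = 1 exactly
  expect_identical(wheatsheaf(tr, X, tr$tip.label)$w, 1)
  # brute-force recomputation from the distance matrix and penalty weights
  f <- tr$tip.label[1:3]
  w <- wheatsheaf(tr, X, f)$w
  Z <- sweep(X, 2, apply(X, 2, sd), "/")
  D <- as.matrix(dist(Z))
  V <- phylo_vcv(tr)
  Dp <- D * (1 + V / max(diag(V))); diag(Dp) <- 0
  w_oracle <- mean(Dp[upper.tri(Dp)]) / mean(Dp[f, f][upper.tri(diag(3))])
  expect_equal(w, w_oracle, tolerance = 1e-12)
  # identical focal phenotypes, dispersed non-focal: w > 1 (here infinite)
  X2 <- X; X2[f, ] <- rep(X2[f[1], ], each = 3)
  expect_warning(wi <- wheatsheaf(tr, X2, f), "identical")
  expect_identical(wi$w, Inf)
  # invariant to relabeling of non-focal taxa and trait permutation
  X3 <- X[, c("v", "u")]
  expect_equal(wheatsheaf(tr, X3, f)$w, w, tolerance = 1e-12)
})

test_that("Wheatsheaf permutation p-value is rank-consistent and smoothed", {
  set.seed(29)
  tr <- make_yule_tree(10, seed = 30)
  X <- simulate_bm(tr, sigma2 = c(1, 1), n = 1, internal = FALSE)
  colnames(X) <- c("u", "v")
  # pick the focal set with the LARGEST mean internal distance: observed w
  # is low, so the permutation p must exceed 0.5
  combs <- combn(tr$tip.label, 3)
  ws <- apply(combs, 2, function(f) wheatsheaf(tr, X, f)$w)
  f_lo <- combs[, which.min(ws)]
  r <- wheatsheaf_pvalue(tr, X, f_lo, n_perm = 999, seed = 31)
  expect_gt(r$p, 0.5)
  expect_gt(r$p, 0)
  # Monte-Carlo error bound: doubling n_perm moves p by < 2/sqrt(n_perm)
  r1 <- wheatsheaf_pvalue(tr, X, combs[, 5], n_perm = 2000, seed = 32)
  r2 <- wheatsheaf_pvalue(tr, X, combs[, 5], n_perm = 4000, seed = 33)
  expect_lt(abs(r1$p - r2$p), 2 / sqrt(2000))
})
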
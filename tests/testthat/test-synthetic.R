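test_that("Yule trees have the right shape, size, and depth", {
  t2 <- make_yule_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2L)
  expect_equal(t2$Nnode, 1L)

  tr <- make_yule_tree(9, seed = 2)
  expect_equal(length(tr$tip.label), 9L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))

  # analytic depth: E[depth] = sum_{k=2..n} 1 / (k * birth)
  n <- 8; birth <- 2
  depths <- vapply(1:2000, function(i) {
    max(ape::node.depth.edgelength(make_yule_tree(n, birth, seed = i)))
  }, 0)
  expected <- sum(1 / ((2:n) * birth))
  expect_lt(abs(mean(depths) - expected) / expected, 0.05)
})

test_that("dataset generation is a pure function of its configuration", {
  cfg <- synthetic_config(n_species = 15, seed = 5)
  d1 <- make_dataset(cfg)
  d2 <- make_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- make_dataset(synthetic_config(n_species = 15, seed = 6))
  expect_false(identical(d1$trait_means, d3$trait_means))
})

test_that("noise-free single-specimen data reproduce the true means", {
  cfg <- synthetic_config(
    n_species = 10, convergence = FALSE, n_males = 1, n_females = 0,
    noise_sd = setNames(rep(0, 6), trait_names()),
    side_jitter_sd = 0, n_missing_breeding = 0, seed = 7)
  ds <- make_dataset(cfg)
  sm <- species_means(specimen_traits(ds$specimens))
  expect_equal(sm[rownames(ds$trait_means), colnames(ds$trait_means)],
               ds$trait_means, tolerance = 1e-10)
})

test_that("generated states are non-constant and behaviour is consistent", {
  ds <- make_dataset(synthetic_config(n_species = 25, seed = 8))
  for (chn in c("breeding", "foraging")) {
    tips <- ds$states[[chn]][seq_len(25)]
    expect_true(length(unique(tips)) == 2L)
  }
  ch <- behavior_characters(ds$behavior)
  known <- names(ch$breeding)
  expect_equal(as.integer(ch$breeding),
               as.integer(ds$states$breeding[known]))
  expect_equal(as.integer(ch$foraging),
               as.integer(ds$states$foraging[names(ch$foraging)]))
  # all measurements positive
  m <- ds$specimens[, !(names(ds$specimens) %in% c("species", "sex"))]
  expect_true(all(as.matrix(m) > 0))
})

test_that("an impossible threshold configuration fails loudly", {
  cfg <- synthetic_config(n_species = 8, root_liability = c(50, 50),
                          liability_sigma2 = 1e-6, seed = 9)
  expect_error(make_dataset(cfg), "20 tries")
})

test_that("fixtures round-trip through the readers", {
  ds <- make_dataset(synthetic_config(n_species = 12, seed = 10))
  dir <- file.path(tempfile("fix"))
  paths <- write_fixture(ds, dir)
  expect_true(all(file.exists(paths)))
  tr <- read_phylogeny(file.path(dir, "tree.nwk"))
  expect_true(ape::all.equal.phylo(tr, ds$tree, use.edge.length = TRUE))
  sp <- suppressMessages(read_specimen_csv(file.path(dir, "specimens.csv")))
  num <- !(names(ds$specimens) %in% c("species", "sex"))
  expect_equal(as.matrix(sp[, num]), as.matrix(ds$specimens[, num]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sp$species, ds$specimens$species)
  bh <- read_behavior_csv(file.path(dir, "behavior.csv"))
  expect_equal(bh$foraging_category, ds$behavior$foraging_category)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$schema, "socioconv-truth/1")
  expect_equal(unlist(truth$states$breeding),
               unname(ds$states$breeding), ignore_attr = TRUE)
})

test_that("the convergent regime pulls social lineages together", {
  # paired datasets (same seed): mean C1 of the social-forager set must be
  # larger with the convergent pull than without it
  set.seed(11)
  c1_on <- c(); c1_off <- c()
  for (i in 1:12) {
    for (conv in c(TRUE, FALSE)) {
      cfg <- synthetic_config(n_species = 40, convergence = conv,
                              seed = 500 + i)
      ds <- make_dataset(cfg)
      mu <- ds$trait_means
      z <- sweep(sweep(mu, 2, colMeans(mu), "-"), 2, apply(mu, 2, sd), "/")
      focal <- names(which(ds$states$foraging[1:40] == 1))
      if (length(focal) < 3 || length(focal) > 37) next
      s <- stayton_indices(ds$tree, z, focal)
      if (conv) c1_on <- c(c1_on, s$C1) else c1_off <- c(c1_off, s$C1)
    }
  }
  expect_gt(mean(c1_on), mean(c1_off))
})
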
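test_that("threshold reconstruction solves degenerate and symmetric cases", {
  t4 <- balanced4()
  all1 <- bin_char(rep(1, 4), c("A", "B", "C", "D"))
  expect_warning(a <- ancestral_threshold(t4, all1, n_gen = 2e4,
                                          sample_every = 20, seed = 1),
                 "constant")
  expect_gt(a$post["5"], 0.9)

  # two social sisters vs two solitary sisters: the root is a coin flip
  sym <- bin_char(c(1, 1, 0, 0), c("A", "B", "C", "D"))
  a2 <- ancestral_threshold(t4, sym, n_gen = 1e5, sample_every = 50,
                            seed = 2)
  expect_lt(abs(a2$post["5"] - 0.5), 0.05)
})

test_that("trace dimensions and tip sign constraints hold in every sample", {
  t4 <- balanced4()
  ch <- bin_char(c(1, 0, 1, 0), c("A", "B", "C", "D"))
  a <- ancestral_threshold(t4, ch, n_gen = 2e4, sample_every = 40,
                           burnin = 0.10, seed = 3)
  nsamp <- floor(2e4 / 40)
  expect_equal(nrow(a$trace), nsamp - floor(0.10 * nsamp))
  expect_equal(ncol(a$trace), 7L)
  for (tip in names(ch)) {
    if (ch[tip] == 1L) expect_true(all(a$trace[, tip] > 0))
    else expect_true(all(a$trace[, tip] <= 0))
  }
  # posterior state probabilities are proper and tips are certain
  expect_true(all(a$post >= 0 & a$post <= 1))
  expect_equal(unname(a$post[names(ch)]), as.numeric(ch))
})

test_that("acceptance rate stays in a healthy band after tuning", {
  for (n in c(10, 60)) {
    tr <- make_yule_tree(n, seed = n)
    ch <- simulate_threshold_states(tr, 0, 1, seed = n + 1)$states[1:n]
    if (length(unique(ch)) < 2) next
    a <- ancestral_threshold(tr, ch, n_gen = 2e4, sample_every = 40,
                             seed = n + 2)
    expect_gt(a$acceptance, 0.1)
    expect_lt(a$acceptance, 0.7)
  }
})

test_that("reconstruction beats a label-shuffled control on simulated truth", {
  set.seed(4)
  tr <- make_yule_tree(50, seed = 44)
  sim <- simulate_threshold_states(tr, 0, 1, seed = 5)
  ch <- sim$states[1:50]
  truth <- sim$states[51:99]
  a <- ancestral_threshold(tr, ch, n_gen = 4e4, sample_every = 40, seed = 6)
  pm <- a$post[as.character(51:99)]
  p_true <- mean(ifelse(truth == 1, pm, 1 - pm))
  expect_gt(p_true, 0.5)
  # shuffled control: same marginal states, destroyed phylogenetic signal
  ch_shuf <- setNames(sample(ch), names(ch))
  a_s <- ancestral_threshold(tr, ch_shuf, n_gen = 4e4, sample_every = 40,
                             seed = 7)
  pm_s <- a_s$post[as.character(51:99)]
  p_shuf <- mean(ifelse(truth == 1, pm_s, 1 - pm_s))
  expect_gt(p_true, p_shuf)
})

test_that("branch-length rescaling leaves posterior states unchanged", {
  tr <- make_yule_tree(20, seed = 8)
  ch <- simulate_threshold_states(tr, 0.3, 1, seed = 9)$states[1:20]
  a1 <- ancestral_threshold(tr, ch, n_gen = 1e5, sample_every = 100,
                            seed = 10)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 2
  a2 <- ancestral_threshold(tr2, ch, n_gen = 1e5, sample_every = 100,
                            seed = 11)
  ints <- as.character(21:39)
  expect_lt(max(abs(a1$post[ints] - a2$post[ints])), 0.08)
})

test_that("forward threshold simulation has the stated invariances", {
  tr <- balanced4()
  # strong positive root liability, tiny rate: all tips in state 1
  s <- simulate_threshold_states(tr, root_liability = 10, sigma2 = 0.01,
                                 seed = 12)
  expect_equal(unname(s$states[1:4]), rep(1L, 4))
  # root liability 0: tip state proportions ~ 0.5 over replicates
  props <- vapply(1:300, function(i) {
    mean(simulate_threshold_states(tr, 0, 1, seed = 1000 + i)$states[1:4])
  }, 0)
  expect_lt(abs(mean(props) - 0.5), 0.05)
  # states invariant to scaling liabilities and rate by c > 0
  s1 <- simulate_threshold_states(tr, 0.2, 1, seed = 13)
  s2 <- simulate_threshold_states(tr, 0.2 * 5, 25, seed = 13)
  expect_equal(s1$states, s2$states)
})
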
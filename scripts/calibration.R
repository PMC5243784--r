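#!/usr/bin/env Rscript
# Nightly-scale null calibration study for every simulation/permutation
# p-value in the package (the test suite runs reduced versions of these).
# Writes a summary table to stdout.
#
# Usage: Rscript scripts/calibration.R [--seed N] [--n-datasets 500]

suppressPackageStartupMessages(library(socioconv))
args <- commandArgs(trailingOnly = TRUE)
opt <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) return(default)
  args[i + 1L]
}
seed <- as.integer(opt("--seed", "1"))
nds <- as.integer(opt("--n-datasets", "500"))
set.seed(seed)

report <- function(name, pv) {
  cat(sprintf("%-28s n=%4d  rej(.05)=%.3f  mean=%.3f  KS p=%.4f\n",
              name, length(pv), mean(pv <= 0.05), mean(pv),
              suppressWarnings(stats::ks.test(pv, "punif")$p.value)))
}

tr15 <- make_yule_tree(15, seed = seed + 1)
pv <- vapply(seq_len(nds), function(i) {
  lab <- setNames(sample(rep(0:1, c(7, 8))), sample(tr15$tip.label))
  x <- simulate_bm(tr15, sigma2 = 1, n = 1, internal = FALSE)
  phylo_ttest(tr15, x, lab, n_sims = 499)$p
}, 0)
report("phylo_ttest", pv)

pv <- vapply(seq_len(nds), function(i) {
  X <- simulate_bm(tr15, sigma2 = rep(1, 3), n = 1, internal = FALSE)
  colnames(X) <- c("a", "b", "c")
  wheatsheaf_pvalue(tr15, X, sample(tr15$tip.label, 5), n_perm = 999)$p
}, 0)
report("wheatsheaf_pvalue", pv)

tr40 <- make_yule_tree(40, seed = seed + 2)
pm <- t(vapply(seq_len(nds), function(i) {
  X <- simulate_bm(tr40, sigma2 = c(1, 1), n = 1, internal = FALSE)
  colnames(X) <- c("a", "b")
  stayton_significance(tr40, X, sample(tr40$tip.label, 8), n_sims = 199)$p
}, c(C1 = 0, C2 = 0, C3 = 0, C4 = 0)))
for (j in colnames(pm)) report(paste0("stayton_significance ", j), pm[, j])

tr15b <- make_yule_tree(15, seed = seed + 3)
pv <- vapply(seq_len(nds), function(i) {
  repeat {
    sA <- socioconv:::.sim_mk2(tr15b, 0.4, 0.4, 1)[, 1]
    sB <- socioconv:::.sim_mk2(tr15b, 0.4, 0.4, 1)[, 1]
    if (length(unique(sA)) == 2L && length(unique(sB)) == 2L) break
  }
  names(sA) <- names(sB) <- tr15b$tip.label
  pagel_correlation(tr15b, sA, sB, n_sims = 199, n_starts = 1,
                    maxit = 200)$p
}, 0)
report("pagel_correlation", pv)
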
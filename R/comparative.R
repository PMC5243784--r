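# Two-group trait comparisons on a phylogeny: plain descriptive statistics,
# a t-test whose null distribution comes from Brownian-motion simulation on
# the tree (so shared ancestry cannot masquerade as a group difference), and
# Holm's step-down multiple-testing correction.

#' Descriptive statistics per behavioural state
#'
#' Plain (non-phylogenetic) mean and standard deviation of each trait within
#' each state, species equally weighted; reported alongside the phylogenetic
#' tests to show absolute trait variability per group.
#'
#' @param traits taxa x traits matrix.
#' @param char named 0/1 character over (a subset of) the taxa.
#' @return data.frame: trait, state, state_name, n, mean, sd. Groups with a
#'   single species get sd 0 with a warning.
#' @export
descriptive_stats <- function(traits, char) {
  taxa <- intersect(rownames(traits), names(char))
  sn <- attr(char, "state_names")
  if (is.null(sn)) sn <- c("state0", "state1")
  char <- char[taxa]
  out <- do.call(rbind, lapply(colnames(traits), function(tr) {
    do.call(rbind, lapply(0:1, function(st) {
      v <- traits[taxa[char == st], tr]
      v <- v[!is.na(v)]
      s <- if (length(v) > 1L) stats::sd(v) else {
        warning("single species in state ", sn[st + 1L], " for trait ", tr,
                "; SD reported as 0")
        0
      }
      data.frame(trait = tr, state = st, state_name = sn[st + 1L],
                 n = length(v), mean = mean(v), sd = s)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Phylogenetic two-group t-test with a simulation null
#'
#' The observed statistic is the pooled-variance two-sample t between the
#' state-0 and state-1 species means. Its null distribution is built by
#' simulating the trait under Brownian motion on the tree (rate estimated
#' from the full trait vector by GLS) and recomputing t for each replicate
#' with the group labels fixed; the two-tailed p-value is
#' `(#{|t_sim| >= |t_obs|} + 1) / (n_sims + 1)`.
#'
#' @param tree a `"phylo"` object.
#' @param x named trait vector covering every tip.
#' @param char named 0/1 character covering every tip (>= 2 species per
#'   state).
#' @param n_sims number of Brownian-motion simulations (default 10000).
#' @param seed optional integer seed.
#' @return list with per-group `n`, `mean`, `sd`, the statistic `t`, the
#'   simulation p-value `p`, `sigma2`, and `n_sims`. A constant trait yields
#'   `p = 1` with a warning.
#' @export
phylo_ttest <- function(tree, x, char, n_sims = 10000, seed = NULL) {
  tree <- validate_phylogeny(tree, warn_zero = FALSE)
  x <- .tip_matrix(tree, x)[, 1L]
  st <- char[tree$tip.label]
  if (anyNA(st) || !all(st %in% 0:1)) stop("states must be 0/1 for every tip")
  g0 <- which(st == 0L); g1 <- which(st == 1L)
  if (length(g0) < 2L || length(g1) < 2L) {
    stop("both states need at least 2 species")
  }
  stats_of <- function(v) {
    n0 <- length(g0); n1 <- length(g1)
    m0 <- mean(v[g0]); m1 <- mean(v[g1])
    s2 <- (sum((v[g0] - m0)^2) + sum((v[g1] - m1)^2)) / (n0 + n1 - 2)
    if (s2 <= 0) return(0)
    (m1 - m0) / sqrt(s2 * (1 / n0 + 1 / n1))
  }
  grp <- list(n = c(length(g0), length(g1)),
              mean = c(mean(x[g0]), mean(x[g1])),
              sd = c(stats::sd(x[g0]), stats::sd(x[g1])))
  if (stats::sd(x) == 0) {
    warning("trait constant across species; p = 1")
    return(c(grp, list(t = 0, p = 1, sigma2 = 0, n_sims = n_sims)))
  }
  t_obs <- stats_of(x)
  fit <- estimate_bm_rate(tree, x)
  if (!is.null(seed)) set.seed(seed)
  sims <- simulate_bm(tree, sigma2 = fit$sigma2, root_state = fit$mu,
                      n = n_sims, internal = FALSE)
  t_sim <- apply(sims, 2L, stats_of)
  p <- (sum(abs(t_sim) >= abs(t_obs)) + 1) / (n_sims + 1)
  c(grp, list(t = t_obs, p = p, sigma2 = unname(fit$sigma2),
              n_sims = n_sims))
}

#' Holm step-down multiple-testing adjustment
#'
#' Sorted ascending, the i-th p-value is multiplied by (m - i + 1), a running
#' maximum is enforced, values are capped at 1, and the input order is
#' restored. Controls the family-wise error rate. Wraps
#' `stats::p.adjust(method = "holm")` behind input validation.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted p-values in the input order.
#' @export
holm_adjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "holm")
}

#' Trait-by-trait phylogenetic t-tests with Holm correction
#'
#' Runs [phylo_ttest()] for every trait column against one behavioural
#' character and Holm-adjusts the p-values across the traits (the family is
#' the set of traits tested within this behaviour).
#'
#' @param tree a `"phylo"` object.
#' @param traits tips x traits matrix covering every tip.
#' @param char named 0/1 character covering every tip.
#' @param n_sims,seed passed to [phylo_ttest()].
#' @return data.frame: trait, n0, mean0, sd0, n1, mean1, sd1, t, p, p_holm.
#' @export
phylo_ttest_table <- function(tree, traits, char, n_sims = 10000,
                              seed = NULL) {
  traits <- .tip_matrix(tree, traits)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(colnames(traits), function(tr) {
    r <- phylo_ttest(tree, traits[, tr], char, n_sims = n_sims)
    data.frame(trait = tr, n0 = r$n[1L], mean0 = r$mean[1L], sd0 = r$sd[1L],
               n1 = r$n[2L], mean1 = r$mean[2L], sd1 = r$sd[2L],
               t = r$t, p = r$p)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p)
  out
}
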
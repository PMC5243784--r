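# Bayesian ancestral state reconstruction of a binary character under the
# liability threshold model.
#
# The observed 0/1 state is the sign of an unobserved continuous liability
# evolving by Brownian motion along the tree. With two states, the liability
# rate and the threshold location are not identifiable separately from the
# liability scale, so the rate is fixed at 1 and the threshold at 0; only the
# node and tip liabilities are sampled. The sampler is a single-site
# random-scan Metropolis chain (compiled kernel) whose tip updates respect
# the observed signs.

# simple ESS from the autocorrelation function, truncated at first negative
.ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

.split_rhat <- function(x) {
  n <- length(x)
  if (n < 8L) return(NA_real_)
  h <- n %/% 2L
  ch <- list(x[seq_len(h)], x[(h + 1L):(2L * h)])
  m <- vapply(ch, mean, 0); v <- vapply(ch, stats::var, 0)
  W <- mean(v); B <- h * stats::var(m)
  if (W == 0) return(NA_real_)
  sqrt(((h - 1) / h * W + B / h) / W)
}

#' Threshold-model ancestral state reconstruction
#'
#' Samples the posterior of node liabilities given observed tip states, with
#' a Brownian-motion prior (rate 1, threshold 0) on the tree. Posterior state
#' probabilities are the per-node fraction of retained samples with liability
#' above the threshold. A "generation" is one full sweep (every node updated
#' once, order re-randomised per sweep); proposal step sizes auto-tune toward
#' ~0.3 acceptance during burn-in and are frozen afterwards.
#'
#' @param tree a `"phylo"` object.
#' @param char named 0/1 vector covering every tip (see
#'   [classify_breeding()]).
#' @param n_gen number of MCMC generations (default 2e6).
#' @param sample_every thinning interval (default 2000).
#' @param burnin fraction of recorded samples discarded (default 0.10).
#' @param seed optional integer seed.
#' @return object of class `"liability_asr"`: list with `trace` (retained
#'   samples x nodes liability matrix; columns are tips in tree order then
#'   internal ape node ids), `post` (named per-node probability of state 1),
#'   `acceptance` (post-burn-in rate), `ess` and `split_rhat` of the root
#'   liability, plus the run settings.
#' @export
ancestral_threshold <- function(tree, char, n_gen = 2e6, sample_every = 2000,
                                burnin = 0.10, seed = NULL) {
  tree <- validate_phylogeny(tree)
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  miss <- setdiff(tree$tip.label, names(char))
  if (length(miss)) stop("no state for tip(s): ", paste(miss, collapse = ", "))
  st <- as.integer(char[tree$tip.label])
  if (anyNA(st) || !all(st %in% 0:1)) stop("states must be 0/1 for every tip")
  if (length(unique(st)) == 1L) {
    warning("character is constant across tips; root posterior will be ",
            "essentially degenerate")
  }
  if (n_gen < 10 * sample_every) stop("n_gen too small for the thinning interval")
  parent <- .parent_vec(tree)
  blen <- .blen_vec(tree)
  tipstate <- c(st, rep(-1L, tree$Nnode))
  # init: tips at +/-1 by state; internal nodes at the mean of descendant
  # tip initial values (postorder accumulation)
  init <- c(ifelse(st == 1L, 1, -1), rep(0, tree$Nnode))
  cnt <- c(rep(1, ntip), rep(0, tree$Nnode))
  post <- .postorder_edges(tree)
  acc <- numeric(ntot); acc[seq_len(ntip)] <- init[seq_len(ntip)]
  for (e in seq_len(nrow(post))) {
    a <- post[e, 1L]; d <- post[e, 2L]
    acc[a] <- acc[a] + acc[d]
    cnt[a] <- cnt[a] + cnt[d]
  }
  internal <- (ntip + 1L):ntot
  init[internal] <- acc[internal] / cnt[internal]
  if (!is.null(seed)) set.seed(seed)
  res <- threshold_mcmc_cpp(parent, blen, tipstate, init,
                            as.double(n_gen), as.double(sample_every),
                            burnin, 0.3)
  samples <- res$samples
  colnames(samples) <- c(tree$tip.label, as.character(internal))
  p1 <- colMeans(samples > 0)
  root_liab <- samples[, as.character(.root_id(tree))]
  structure(list(
    trace = samples,
    post = p1,
    acceptance = res$acceptance,
    ess_root = .ess(root_liab),
    split_rhat_root = .split_rhat(root_liab),
    n_gen = n_gen, sample_every = sample_every, burnin = burnin,
    state_names = attr(char, "state_names"),
    tree = tree
  ), class = "liability_asr")
}

#' @export
print.liability_asr <- function(x, ...) {
  root <- as.character(.root_id(x$tree))
  cat("Threshold-model ancestral reconstruction\n")
  cat(sprintf("  %d retained samples (%g generations, thin %g, burn-in %g%%)\n",
              nrow(x$trace), x$n_gen, x$sample_every, 100 * x$burnin))
  cat(sprintf("  acceptance %.2f | root ESS %.0f | root split-Rhat %.3f\n",
              x$acceptance, x$ess_root, x$split_rhat_root))
  s1 <- if (!is.null(x$state_names)) x$state_names[2L] else "state 1"
  cat(sprintf("  P(root = %s) = %.3f\n", s1, x$post[root]))
  invisible(x)
}

#' Forward-simulate a binary character under the threshold model
#'
#' Liabilities evolve by Brownian motion from `root_liability`; the observed
#' state is the indicator that the liability exceeds 0. States are invariant
#' to rescaling liabilities and rate by a common positive factor.
#'
#' @param tree a `"phylo"` object.
#' @param root_liability root liability value.
#' @param sigma2 liability BM rate (default 1).
#' @param seed optional integer seed.
#' @return list with `liabilities` (named, all nodes) and `states` (named
#'   0/1 over all nodes; the tip entries form the observable character).
#' @export
simulate_threshold_states <- function(tree, root_liability = 0, sigma2 = 1,
                                      seed = NULL) {
  liab <- simulate_bm(tree, sigma2 = sigma2, root_state = root_liability,
                      n = 1, internal = TRUE, seed = seed)
  states <- as.integer(liab > 0)
  names(states) <- names(liab)
  list(liabilities = liab, states = states)
}
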
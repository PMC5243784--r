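# Convergence metrics for a focal set of taxa: Stayton's C1-C4 (trajectories
# through phenotype space, judged against reconstructed ancestors) with
# Brownian-motion simulation significance, and the Wheatsheaf index
# (phylogenetically penalised phenotypic clustering) with permutation
# significance.

# per-pair path structures, computed once and reused across null replicates
.pair_structs <- function(tree, focal) {
  parent <- .parent_vec(tree)
  ntip <- length(tree$tip.label)
  tip_id <- match(focal, tree$tip.label)
  M <- ape::mrca(tree)
  pairs <- utils::combn(seq_along(focal), 2L)
  lapply(seq_len(ncol(pairs)), function(k) {
    i <- tip_id[pairs[1L, k]]; j <- tip_id[pairs[2L, k]]
    m <- M[i, j]
    list(a = i, b = j, mrca = m,
         path_a = .path_to(parent, i, m),
         path_b = .path_to(parent, j, m))
  })
}

# Euclidean step length of every edge given node coordinates X (nodes x p)
.edge_steps <- function(tree, X, squared = FALSE) {
  d2 <- rowSums((X[tree$edge[, 1L], , drop = FALSE] -
                   X[tree$edge[, 2L], , drop = FALSE])^2)
  if (squared) d2 else sqrt(d2)
}

# core index computation from node coordinates; ps = .pair_structs output
.stayton_core <- function(tree, X, ps, squared = FALSE) {
  step <- .edge_steps(tree, X, squared)
  tot_tree <- sum(step)
  # edge index by child node
  echild <- integer(length(tree$tip.label) + tree$Nnode)
  echild[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  out <- matrix(NA_real_, length(ps), 7L,
                dimnames = list(NULL, c("Dtip", "Dmax", "C1", "C2", "C3",
                                        "C4", "Ltot")))
  for (k in seq_along(ps)) {
    pr <- ps[[k]]
    A <- X[pr$path_a, , drop = FALSE]
    B <- X[pr$path_b, , drop = FALSE]
    cross <- outer(rowSums(A^2), rep(1, nrow(B))) +
      outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
    cross[cross < 0] <- 0
    D <- sqrt(cross)
    Dtip <- D[1L, 1L]
    Dmax <- max(D)
    # total evolution along the two lineages from the MRCA to both tips
    ed <- c(pr$path_a[pr$path_a != pr$mrca], pr$path_b[pr$path_b != pr$mrca])
    Ltot <- sum(step[echild[ed]])
    if (Dmax <= 0) next      # caller warns and skips
    C2 <- Dmax - Dtip
    out[k, ] <- c(Dtip, Dmax, 1 - Dtip / Dmax, C2,
                  if (Ltot > 0) C2 / Ltot else NA_real_,
                  if (tot_tree > 0) C2 / tot_tree else NA_real_, Ltot)
  }
  out
}

.check_focal <- function(tree, traits, focal) {
  focal <- trimws(focal)
  unknown <- setdiff(focal, tree$tip.label)
  if (length(unknown)) stop("focal taxa not in tree: ",
                            paste(unknown, collapse = ", "))
  if (length(focal) < 2L) stop("need at least 2 focal taxa")
  focal
}

#' Stayton's C1-C4 convergence indices
#'
#' For each focal pair (a, b): `Dtip` is the Euclidean distance between the
#' two tip phenotypes and `Dmax` the maximum distance between any node on
#' a's root-path and any node on b's root-path, the paths truncated at (and
#' including) their MRCA, with the tips themselves included. Then
#' `C1 = 1 - Dtip/Dmax` (fraction of the maximal ancestral dissimilarity
#' that has been closed), `C2 = Dmax - Dtip`, `C3 = C2 / (total evolution
#' along both lineages from the MRCA to the tips)`, and `C4 = C2 / (total
#' evolution over every edge of the tree)`. "Total evolution" sums the
#' Euclidean ancestor-to-descendant step lengths (set `squared = TRUE` to sum
#' squared steps instead). Pairwise values are averaged (unweighted) over all
#' focal pairs; pairs with `Dmax = 0` are skipped with a warning.
#'
#' @param tree a `"phylo"` object.
#' @param traits tips x traits matrix (taxa rownames), complete for all tips.
#' @param focal character vector of focal taxa (>= 2).
#' @param anc ancestral states: a matrix as returned by [ancestral_ml()]
#'   (tips + internal nodes, ape order). Defaults to `ancestral_ml(tree,
#'   traits)`.
#' @param squared use squared step lengths in the C3/C4 denominators.
#' @return object of class `"convergence_indices"`: list with `C1`-`C4`,
#'   `pairs` (per-pair data.frame), `focal`, `n_pairs`, `n_skipped`.
#' @export
stayton_indices <- function(tree, traits, focal, anc = NULL,
                            squared = FALSE) {
  tree <- validate_phylogeny(tree, warn_zero = FALSE)
  traits <- .tip_matrix(tree, traits)
  if (anyNA(traits)) stop("missing trait values")
  focal <- .check_focal(tree, traits, focal)
  if (is.null(anc)) anc <- ancestral_ml(tree, traits)
  ntot <- length(tree$tip.label) + tree$Nnode
  if (nrow(anc) != ntot) stop("anc must cover all tips and internal nodes")
  ps <- .pair_structs(tree, focal)
  res <- .stayton_core(tree, anc, ps, squared)
  skipped <- is.na(res[, "C1"]) & !is.na(res[, "Dtip"]) & res[, "Dmax"] <= 0
  bad <- rowSums(is.na(res[, c("C1", "C2"), drop = FALSE])) > 0
  if (any(bad)) {
    warning(sum(bad), " focal pair(s) skipped (Dmax = 0: identical ",
            "phenotypes along both paths)")
  }
  pairs_df <- data.frame(
    tip1 = vapply(ps, function(p) tree$tip.label[p$a], ""),
    tip2 = vapply(ps, function(p) tree$tip.label[p$b], ""),
    res[, c("Dtip", "Dmax", "C1", "C2", "C3", "C4"), drop = FALSE]
  )
  structure(list(
    C1 = mean(res[, "C1"], na.rm = TRUE),
    C2 = mean(res[, "C2"], na.rm = TRUE),
    C3 = mean(res[, "C3"], na.rm = TRUE),
    C4 = mean(res[, "C4"], na.rm = TRUE),
    pairs = pairs_df, focal = focal,
    n_pairs = length(ps), n_skipped = sum(bad)
  ), class = "convergence_indices")
}

#' @export
print.convergence_indices <- function(x, ...) {
  cat("Stayton convergence indices over", x$n_pairs, "focal pairs\n")
  cat(sprintf("  C1 = %.4f  C2 = %.4f  C3 = %.4f  C4 = %.4f\n",
              x$C1, x$C2, x$C3, x$C4))
  if (!is.null(x$p)) {
    cat(sprintf("  p:   %.4g     %.4g     %.4g     %.4g  (%d BM simulations)\n",
                x$p["C1"], x$p["C2"], x$p["C3"], x$p["C4"], x$n_sims))
  }
  invisible(x)
}

#' Simulation significance for the Stayton indices
#'
#' Simulates trait evolution under Brownian motion (rates and trait
#' covariance estimated from the observed data by GLS), re-estimates
#' ancestral states per replicate with the same ML estimator used for the
#' observed data, recomputes C1-C4 for the same focal set, and reports
#' `p = (#{sim >= observed} + 1) / (n_sims + 1)` per index.
#'
#' @inheritParams stayton_indices
#' @param n_sims number of Brownian-motion simulations (>= 100).
#' @param seed optional integer seed.
#' @param joint simulate traits jointly with the estimated evolutionary
#'   covariance (default) or independently per trait.
#' @return a `"convergence_indices"` object with added `p` (named vector),
#'   `n_sims`, and `sim` (n_sims x 4 matrix of simulated index values).
#' @export
stayton_significance <- function(tree, traits, focal, n_sims = 1000,
                                 seed = NULL, joint = TRUE, squared = FALSE) {
  if (n_sims < 100) stop("n_sims must be >= 100")
  tree <- validate_phylogeny(tree, warn_zero = FALSE)
  traits <- .tip_matrix(tree, traits)
  W <- anc_operator(tree)
  obs <- stayton_indices(tree, traits, focal,
                         anc = ancestral_ml(tree, traits, W = W),
                         squared = squared)
  fit <- estimate_bm_rate(tree, traits)
  if (!is.null(seed)) set.seed(seed)
  R <- if (joint) fit$R else diag(fit$sigma2, length(fit$sigma2))
  ntip <- length(tree$tip.label)
  sims <- simulate_bm(tree, R = R, root_state = fit$mu, n = n_sims,
                      internal = FALSE)
  if (length(dim(sims)) < 3L) sims <- array(sims, c(dim(sims)[1L], 1L, n_sims))
  ps <- .pair_structs(tree, obs$focal)
  simval <- matrix(NA_real_, n_sims, 4L,
                   dimnames = list(NULL, c("C1", "C2", "C3", "C4")))
  for (i in seq_len(n_sims)) {
    y <- sims[, , i, drop = TRUE]
    y <- matrix(y, nrow = ntip, dimnames = list(tree$tip.label, NULL))
    anc <- rbind(y, W %*% y)
    res <- .stayton_core(tree, anc, ps, squared)
    simval[i, ] <- colMeans(res[, c("C1", "C2", "C3", "C4"), drop = FALSE],
                            na.rm = TRUE)
  }
  obsval <- c(C1 = obs$C1, C2 = obs$C2, C3 = obs$C3, C4 = obs$C4)
  p <- vapply(colnames(simval), function(j) {
    (sum(simval[, j] >= obsval[j], na.rm = TRUE) + 1) / (n_sims + 1)
  }, 0)
  obs$p <- p
  obs$n_sims <- n_sims
  obs$sim <- simval
  obs
}

# standardized, phylogenetically penalised distance matrix shared by
# wheatsheaf() and wheatsheaf_pvalue()
.wheat_setup <- function(tree, traits, standardize) {
  traits <- .tip_matrix(tree, traits)
  if (anyNA(traits)) stop("missing trait values")
  if (standardize) {
    s <- apply(traits, 2L, stats::sd)
    s[s == 0] <- 1
    traits <- sweep(traits, 2L, s, "/")
  }
  D <- as.matrix(stats::dist(traits))
  V <- phylo_vcv(tree)
  Dp <- D * (1 + V / max(diag(V)))
  diag(Dp) <- 0
  Dp
}

.mean_offdiag <- function(M, idx = NULL) {
  if (is.null(idx)) {
    n <- nrow(M)
    sum(M) / (n * (n - 1))
  } else {
    k <- length(idx)
    sum(M[idx, idx]) / (k * (k - 1))
  }
}

#' Wheatsheaf index of convergence strength
#'
#' Quantifies how tightly a focal set clusters in phenotype space relative to
#' the clade as a whole, discounting similarity attributable to shared
#' ancestry. Traits are standardised to unit variance (default), pairwise
#' Euclidean distances are penalised by shared history —
#' `d'(i, j) = d(i, j) * (1 + v(i, j) / max depth)` with `v` from
#' [phylo_vcv()] — and `w = mean(d' over all pairs) / mean(d' over
#' focal-focal pairs)`. Larger `w` means stronger convergence. Identical
#' focal phenotypes give `w = Inf` with a warning; `focal` equal to all taxa
#' gives `w = 1` exactly.
#'
#' @inheritParams stayton_indices
#' @param standardize z-scale each trait before computing distances.
#' @return list with `w`, `focal`, `n_taxa`.
#' @export
wheatsheaf <- function(tree, traits, focal, standardize = TRUE) {
  tree <- validate_phylogeny(tree, warn_zero = FALSE)
  focal <- .check_focal(tree, traits, focal)
  if (length(focal) >= length(tree$tip.label)) {
    if (setequal(focal, tree$tip.label)) {
      return(list(w = 1, focal = focal, n_taxa = length(tree$tip.label)))
    }
  }
  Dp <- .wheat_setup(tree, traits, standardize)
  fidx <- match(focal, rownames(Dp))
  mf <- .mean_offdiag(Dp, fidx)
  if (mf == 0) {
    warning("focal phenotypes identical: Wheatsheaf index is infinite")
    return(list(w = Inf, focal = focal, n_taxa = nrow(Dp)))
  }
  list(w = .mean_offdiag(Dp) / mf, focal = focal, n_taxa = nrow(Dp))
}

#' Permutation significance for the Wheatsheaf index
#'
#' Permutes which taxa carry the focal label (the focal-set size is fixed),
#' recomputes `w` for each permutation, and reports
#' `p = (#{w_perm >= w_obs} + 1) / (n_perm + 1)`.
#'
#' @inheritParams wheatsheaf
#' @param n_perm number of label permutations (>= 999).
#' @param seed optional integer seed.
#' @return list with `w`, `p`, `n_perm`, `focal`.
#' @export
wheatsheaf_pvalue <- function(tree, traits, focal, n_perm = 10000,
                              seed = NULL, standardize = TRUE) {
  if (n_perm < 999) stop("n_perm must be >= 999")
  tree <- validate_phylogeny(tree, warn_zero = FALSE)
  focal <- .check_focal(tree, traits, focal)
  Dp <- .wheat_setup(tree, traits, standardize)
  n <- nrow(Dp)
  k <- length(focal)
  mall <- .mean_offdiag(Dp)
  mf_obs <- .mean_offdiag(Dp, match(focal, rownames(Dp)))
  w_obs <- if (mf_obs > 0) mall / mf_obs else Inf
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, k)
    mf <- .mean_offdiag(Dp, idx)
    wp <- if (mf > 0) mall / mf else Inf
    if (wp >= w_obs) count <- count + 1L
  }
  list(w = w_obs, p = (count + 1) / (n_perm + 1), n_perm = n_perm,
       focal = focal)
}
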
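# Continuous-trait machinery: Brownian-motion and Ornstein-Uhlenbeck
# simulation along trees, GLS rate estimation, and ML ancestral states.
#
# Simulations are vectorised across replicates: one preorder pass over the
# edges draws the Gaussian increments for all replicates at once, so the
# simulation nulls used by the convergence and group tests stay cheap at
# thousands of replicates.

# symmetric PSD square root (eigen-based; tolerates semidefinite R)
.sqrtm_psd <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Simulate Brownian motion along a phylogeny
#'
#' Forward simulation from the root: the root takes `root_state` and each
#' child equals its parent plus a Gaussian increment with variance
#' `sigma2 * branch length` (multivariate: covariance `R * branch length`).
#'
#' @param tree a `"phylo"` object.
#' @param sigma2 per-trait rate(s); ignored when `R` is given.
#' @param root_state root value(s), recycled to the number of traits.
#' @param R optional trait x trait evolutionary covariance matrix.
#' @param n number of independent replicates.
#' @param internal return internal-node values as well (default `TRUE`).
#' @param seed optional integer seed.
#' @return With one trait and `n = 1`, a named vector over nodes; one trait
#'   and `n > 1`, a nodes x n matrix; several traits and `n = 1`, a nodes x
#'   traits matrix; otherwise a nodes x traits x n array. Tips come first in
#'   `tree$tip.label` order, then internal nodes labelled by ape node id.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_state = 0, R = NULL, n = 1,
                        internal = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(R)) {
    sigma2 <- as.numeric(sigma2)
    if (any(sigma2 < 0)) stop("sigma2 must be >= 0")
    p <- length(sigma2)
    Rhalf <- if (p == 1L) matrix(sqrt(sigma2)) else diag(sqrt(sigma2), p)
  } else {
    R <- as.matrix(R)
    p <- nrow(R)
    Rhalf <- .sqrtm_psd(R)
  }
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  root_state <- rep_len(as.numeric(root_state), p)
  X <- array(0, dim = c(ntot, p, n))
  root <- .root_id(tree)
  X[root, , ] <- root_state
  pre <- .preorder_edges(tree)
  for (e in seq_len(nrow(pre))) {
    anc <- pre[e, 1L]; des <- pre[e, 2L]; bl <- pre[e, 3L]
    eps <- matrix(rnorm(p * n), n, p) %*% Rhalf * sqrt(bl)
    X[des, , ] <- X[anc, , ] + t(eps)
  }
  .shape_sim_output(X, tree, internal)
}

.shape_sim_output <- function(X, tree, internal) {
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  node_names <- c(tree$tip.label, as.character((ntip + 1L):ntot))
  keep <- if (internal) seq_len(ntot) else seq_len(ntip)
  X <- X[keep, , , drop = FALSE]
  dimnames(X) <- list(node_names[keep], NULL, NULL)
  p <- dim(X)[2L]; n <- dim(X)[3L]
  if (p == 1L && n == 1L) return(setNames(X[, 1L, 1L], rownames(X)))
  if (p == 1L) return(X[, 1L, ])
  if (n == 1L) return(X[, , 1L])
  X
}

#' Simulate an Ornstein-Uhlenbeck process along a phylogeny
#'
#' Exact edge-wise transitions: along an edge of length t in regime with
#' optimum theta, `child ~ Normal(theta + (parent - theta) e^{-alpha t},
#' sigma2 (1 - e^{-2 alpha t}) / (2 alpha))`. The `alpha = 0` limit is handled
#' analytically and reduces to Brownian motion. Traits evolve independently;
#' per-edge regimes allow a convergent pull toward a shared optimum on a
#' subset of lineages.
#'
#' @param tree a `"phylo"` object.
#' @param alpha pull strength (>= 0, units 1/time), scalar.
#' @param theta optimum; either a vector of length p (one regime) or a
#'   regimes x p matrix used together with `edge_regimes`.
#' @param sigma2 per-trait diffusion rate(s), length p.
#' @param root_state root value(s), recycled to p.
#' @param edge_regimes integer vector over `tree$edge` rows indexing rows of
#'   `theta` (required when `theta` is a matrix).
#' @param n replicates; @param internal,seed as in [simulate_bm()].
#' @inheritParams simulate_bm
#' @return shaped as in [simulate_bm()].
#' @export
simulate_ou <- function(tree, alpha, theta, sigma2, root_state = 0,
                        edge_regimes = NULL, n = 1, internal = TRUE,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(alpha) != 1L || alpha < 0) stop("alpha must be a scalar >= 0")
  theta <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1L)
  p <- ncol(theta)
  sigma2 <- rep_len(as.numeric(sigma2), p)
  if (any(sigma2 < 0)) stop("sigma2 must be >= 0")
  nedge <- nrow(tree$edge)
  if (is.null(edge_regimes)) {
    if (nrow(theta) != 1L) stop("edge_regimes required for multiple regimes")
    edge_regimes <- rep(1L, nedge)
  }
  if (length(edge_regimes) != nedge) stop("edge_regimes must label every edge")
  if (any(is.na(edge_regimes)) || any(edge_regimes < 1L) ||
      any(edge_regimes > nrow(theta))) stop("invalid regime index")
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  root_state <- rep_len(as.numeric(root_state), p)
  X <- array(0, dim = c(ntot, p, n))
  X[.root_id(tree), , ] <- root_state
  # map preorder edge rows back to original edge rows for regime lookup
  tr <- ape::reorder.phylo(tree, "cladewise")
  ord <- match(paste(tr$edge[, 1L], tr$edge[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  for (e in seq_len(nrow(tr$edge))) {
    anc <- tr$edge[e, 1L]; des <- tr$edge[e, 2L]; bl <- tr$edge.length[e]
    th <- theta[edge_regimes[ord[e]], ]
    if (alpha == 0) {
      m <- X[anc, , , drop = FALSE]
      v <- sigma2 * bl
    } else {
      w <- exp(-alpha * bl)
      m <- array(th, dim = c(1L, p, n)) +
        (X[anc, , , drop = FALSE] - array(th, dim = c(1L, p, n))) * w
      v <- sigma2 * (-expm1(-2 * alpha * bl)) / (2 * alpha)
    }
    eps <- t(matrix(rnorm(p * n), n, p) * rep(sqrt(v), each = n))
    X[des, , ] <- m[1L, , ] + eps
  }
  .shape_sim_output(X, tree, internal)
}

# Cholesky with epsilon fallback for degenerate covariances (duplicate or
# zero-length tips). The epsilon is applied only inside the inversion, never
# to the stored tree.
.chol_safe <- function(C) {
  L <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(L)) {
    eps <- 1e-8 * max(diag(C))
    warning("singular phylogenetic covariance; regularized with epsilon ",
            format(eps))
    L <- chol(C + diag(eps, nrow(C)))
  }
  L
}

#' Estimate Brownian-motion rates by generalized least squares
#'
#' REML-flavoured GLS estimator: with `C = phylo_vcv(tree)` and GLS root mean
#' `mu = (1' C^-1 y) / (1' C^-1 1)`, the rate is
#' `(y - mu)' C^-1 (y - mu) / (n - 1)`; for several traits the full
#' evolutionary covariance `R` is the matching cross-product matrix. Works on
#' polytomous trees and equals the independent-contrasts estimator on binary
#' trees.
#'
#' @param tree a `"phylo"` object.
#' @param x named tip vector, or tips x traits matrix with taxa rownames.
#' @return list with `sigma2` (per-trait rates), `R` (trait covariance
#'   matrix) and `mu` (GLS root means).
#' @export
estimate_bm_rate <- function(tree, x) {
  x <- .tip_matrix(tree, x)
  if (anyNA(x)) stop("missing tip values")
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 tips")
  C <- phylo_vcv(tree)
  L <- .chol_safe(C)
  Z <- backsolve(L, x, transpose = TRUE)        # L^-T x
  one <- backsolve(L, rep(1, n), transpose = TRUE)
  mu <- drop(crossprod(one, Z)) / sum(one^2)
  Zc <- Z - outer(one, mu)
  R <- crossprod(Zc) / (n - 1)
  dimnames(R) <- list(colnames(x), colnames(x))
  list(sigma2 = setNames(diag(R), colnames(x)), R = R, mu = mu)
}

# coerce tip data to a tips x traits matrix ordered as tree$tip.label
.tip_matrix <- function(tree, x) {
  if (is.null(dim(x))) {
    if (is.null(names(x))) stop("tip values must be named")
    x <- matrix(x, ncol = 1L, dimnames = list(names(x), "trait"))
  }
  miss <- setdiff(tree$tip.label, rownames(x))
  if (length(miss)) stop("no data for tip(s): ", paste(miss, collapse = ", "))
  x[tree$tip.label, , drop = FALSE]
}

#' Linear operator mapping tip values to ML ancestral states
#'
#' Under Brownian motion the ML (GLS conditional-mean, equivalently
#' re-rooting) ancestral estimates are linear in the tip values:
#' `anc = W %*% y`. W depends only on the tree, so it is computed once and
#' reused across all simulation replicates of a null distribution.
#'
#' @param tree a `"phylo"` object.
#' @return an (internal nodes) x (tips) matrix; rownames are ape node ids.
#' @export
anc_operator <- function(tree) {
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  depth <- .node_depths(tree)
  M <- ape::mrca(tree, full = TRUE)     # node id of the MRCA of every pair
  Cfull <- matrix(depth[M], ntot, ntot)
  tips <- seq_len(ntip)
  nodes <- (ntip + 1L):ntot
  C <- Cfull[tips, tips, drop = FALSE]
  Cav <- Cfull[nodes, tips, drop = FALSE]
  L <- .chol_safe(C)
  Cinv <- chol2inv(L)
  w <- colSums(Cinv) / sum(Cinv)            # GLS mean weights
  W <- matrix(rep(w, each = length(nodes)), length(nodes), ntip) +
    Cav %*% Cinv %*% (diag(ntip) - matrix(1, ntip, 1) %*% t(w))
  dimnames(W) <- list(as.character(nodes), tree$tip.label)
  W
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' GLS conditional means given the tip values (the re-rooting formulation);
#' tips are constraints, not estimates, so the returned matrix carries the
#' observations themselves in its tip rows.
#'
#' @param tree a `"phylo"` object.
#' @param x named tip vector or tips x traits matrix.
#' @param W optional precomputed operator from [anc_operator()].
#' @return (tips + internal nodes) x traits matrix; tips first in
#'   `tree$tip.label` order, then internal nodes named by ape node id.
#'   Attribute `"method"` is `"ML-BM"`.
#' @export
ancestral_ml <- function(tree, x, W = NULL) {
  x <- .tip_matrix(tree, x)
  if (anyNA(x)) stop("missing tip values")
  if (is.null(W)) W <- anc_operator(tree)
  anc <- W %*% x
  out <- rbind(x, anc)
  attr(out, "method") <- "ML-BM"
  out
}
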
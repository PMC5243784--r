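# Shared builders for the test suite. All fixtures are generated in code.

# balanced 4-tip tree with unit branches
balanced4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

# a small specimen table: one row per specimen, traits around given means
make_specimens <- function(species, n_each = 2, means = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(means)) {
    means <- c(wing = 100, outer_tail = 60, middle_tail = 45,
               tarsus = 10, bill_length = 7, bill_width = 5)
  }
  rows <- lapply(species, function(sp) {
    data.frame(
      species = sp,
      sex = rep(c("M", "F"), length.out = n_each),
      wing = rnorm(n_each, means["wing"], 1),
      outer_tail_L = rnorm(n_each, means["outer_tail"], 1),
      outer_tail_R = rnorm(n_each, means["outer_tail"], 1),
      middle_tail = rnorm(n_each, means["middle_tail"], 1),
      tarsus_L = rnorm(n_each, means["tarsus"], 0.2),
      tarsus_R = rnorm(n_each, means["tarsus"], 0.2),
      bill_length = rnorm(n_each, means["bill_length"], 0.2),
      bill_width = rnorm(n_each, means["bill_width"], 0.2),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# named binary character with state names
bin_char <- function(states, names, state_names = c("solitary", "social")) {
  s <- as.integer(states)
  names(s) <- names
  attr(s, "state_names") <- state_names
  s
}

# brute-force joint likelihood of two binary characters by enumerating all
# internal joint states; transition probabilities via Matrix::expm
# (independent of the package's eigendecomposition/Taylor code path)
brute_pagel_loglik <- function(tree, sA, sB, rates8, root = "stationary") {
  Q <- matrix(0, 4, 4)
  Q[1, 3] <- rates8[1]; Q[2, 4] <- rates8[2]
  Q[3, 1] <- rates8[3]; Q[4, 2] <- rates8[4]
  Q[1, 2] <- rates8[5]; Q[3, 4] <- rates8[6]
  Q[2, 1] <- rates8[7]; Q[4, 3] <- rates8[8]
  diag(Q) <- -rowSums(Q)
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  if (root == "stationary") {
    e <- eigen(t(Q))
    v <- Re(e$vectors[, which.min(abs(e$values))])
    pi0 <- v / sum(v)
  } else {
    pi0 <- rep(0.25, 4)
  }
  tipj <- 2L * sA[tree$tip.label] + sB[tree$tip.label] + 1L
  ints <- (ntip + 1L):ntot
  grid <- as.matrix(expand.grid(rep(list(1:4), length(ints))))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(ntot)
    st[seq_len(ntip)] <- tipj
    st[ints] <- grid[g, ]
    pr <- pi0[st[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * Ps[[e]][st[tree$edge[e, 1L]], st[tree$edge[e, 2L]]]
    }
    tot <- tot + pr
  }
  log(tot)
}

# simulate a non-constant pair of binary characters on a tree
sim_char_pair <- function(tree, q = 0.4, max_tries = 50) {
  for (i in seq_len(max_tries)) {
    sA <- socioconv:::.sim_mk2(tree, q, q, 1)[, 1]
    sB <- socioconv:::.sim_mk2(tree, q, q, 1)[, 1]
    if (length(unique(sA)) == 2L && length(unique(sB)) == 2L) {
      names(sA) <- names(sB) <- tree$tip.label
      return(list(a = sA, b = sB))
    }
  }
  stop("could not simulate non-constant characters")
}
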
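# Synthetic study-system generator: a Yule tree, two correlated social
# characters produced by a bivariate liability threshold process, species
# trait means evolving by Brownian motion (optionally with a convergent
# Ornstein-Uhlenbeck pull toward a shared optimum on social lineages), and
# specimen-level measurements with measurement noise and left/right jitter.
# Everything is a pure function of the configuration, so a fixed seed gives
# bit-identical datasets.

#' Simulate a Yule (pure-birth) tree with exactly n tips
#'
#' Forward construction: starting from a root with two lineages, waiting
#' times between speciations are Exponential(k * birth_rate) while k lineages
#' are alive, a uniformly chosen lineage splits at each event, and growth
#' stops at the moment the (n+1)-th event would occur, so the expected
#' root-to-tip depth is `sum_{k=2..n} 1/(k * birth_rate)`. The tree is
#' ultrametric.
#'
#' @param n number of tips (>= 2).
#' @param birth_rate speciation rate (> 0), per unit time.
#' @param seed optional integer seed.
#' @return a `"phylo"` object with tips `t1..tn`.
#' @export
make_yule_tree <- function(n, birth_rate = 1, seed = NULL) {
  stopifnot(n >= 2L, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  # active lineages: parent internal node (creation index) and start time
  par <- c(1L, 1L); start <- c(0, 0)
  n_int <- 1L
  t_now <- 0
  edges_a <- integer(0); edges_d <- integer(0); edges_l <- numeric(0)
  while (length(par) < n) {
    k <- length(par)
    t_now <- t_now + rexp(1L, k * birth_rate)
    i <- sample.int(k, 1L)
    n_int <- n_int + 1L
    edges_a <- c(edges_a, par[i]); edges_d <- c(edges_d, n_int)
    edges_l <- c(edges_l, t_now - start[i])
    par <- c(par[-i], n_int, n_int)
    start <- c(start[-i], t_now, t_now)
  }
  t_end <- t_now + rexp(1L, n * birth_rate)
  # terminal edges
  tip_order <- sample.int(n)            # random tip labelling
  edges_a <- c(edges_a, par); edges_d <- c(edges_d, n_int + seq_len(n))
  edges_l <- c(edges_l, t_end - start)
  # renumber: tips 1..n, internal creation index j -> n + j
  is_tip <- edges_d > n_int
  desc <- integer(length(edges_d))
  desc[is_tip] <- tip_order[edges_d[is_tip] - n_int]
  desc[!is_tip] <- edges_d[!is_tip] + n
  anc <- edges_a + n
  tree <- list(edge = cbind(anc, desc), edge.length = edges_l,
               tip.label = paste0("t", seq_len(n)), Nnode = n_int)
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  tree <- ape::reorder.phylo(tree, "cladewise")
  validate_phylogeny(tree)
}

# Trait scale anchors on the familiar mm scale of swallow morphometrics:
# baseline (root) means and across-species SDs, and the optimum social
# lineages are pulled toward under the convergent regime.
.TRAIT_MEANS <- c(wing = 110.73, outer_tail = 61.25, tail_fork = 16.94,
                  tarsus = 8.16, bill_length = 6.93, bill_width = 5.23)
.TRAIT_SDS <- c(wing = 13.15, outer_tail = 21.70, tail_fork = 19.85,
                tarsus = 1.77, bill_length = 1.61, bill_width = 1.09)
.THETA_SOCIAL <- c(wing = 104.95, outer_tail = 55.00, tail_fork = 12.08,
                   tarsus = 8.11, bill_length = 6.27, bill_width = 4.80)
# measurement + individual noise, mm: ruler traits ~2 mm, caliper traits
# ~0.3 mm, matching the instruments' precision and within-species variation
.NOISE_SD <- c(wing = 2.0, outer_tail = 2.0, tail_fork = 2.0,
               tarsus = 0.3, bill_length = 0.3, bill_width = 0.2)

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the swallow-like study conditions: 73 species, two
#' correlated social characters with a socially inclined root, six traits on
#' the mm scale of the study's descriptive table, a convergent OU pull of
#' strength `alpha_height / tree height` toward the social optimum on
#' group-foraging lineages, and 5 male + 5 female specimens per species.
#'
#' @param n_species number of species (>= 4).
#' @param birth_rate Yule speciation rate.
#' @param rho cross-character liability correlation in [-1, 1].
#' @param root_liability length-2 vector (breeding, foraging) of root
#'   liabilities; positive favours the social state at the root.
#' @param liability_sigma2 liability BM rate.
#' @param trait_means,trait_sds named per-trait root means and across-species
#'   SDs (mm); the BM rate per trait is `sd^2 / tree height`.
#' @param theta_social named per-trait social optimum (mm).
#' @param convergence logical: apply the OU pull on social-foraging lineages.
#' @param alpha_height dimensionless pull strength `alpha * tree height`.
#' @param n_males,n_females specimens per species.
#' @param noise_sd named per-trait specimen noise SD (mm).
#' @param side_jitter_sd left/right measurement jitter SD (mm).
#' @param n_missing_breeding species with unknown breeding group size.
#' @param seed master seed (integer).
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_species = 73, birth_rate = 1, rho = 0.6,
                             root_liability = c(0.5, 0.5),
                             liability_sigma2 = 1,
                             trait_means = .TRAIT_MEANS,
                             trait_sds = .TRAIT_SDS,
                             theta_social = .THETA_SOCIAL,
                             convergence = TRUE, alpha_height = 3,
                             n_males = 5, n_females = 5,
                             noise_sd = .NOISE_SD, side_jitter_sd = 0.5,
                             n_missing_breeding = 1, seed = 1) {
  stopifnot(n_species >= 4L, abs(rho) <= 1, liability_sigma2 >= 0,
            alpha_height >= 0, n_males + n_females >= 1)
  traits <- names(trait_means)
  stopifnot(identical(traits, names(trait_sds)),
            identical(traits, names(theta_social)),
            identical(traits, names(noise_sd)))
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a complete synthetic dataset
#'
#' Steps, all driven by the master seed: (1) Yule tree; (2) bivariate
#' liability Brownian motion with correlation `rho` thresholded at 0 into
#' breeding and foraging states at every node (regenerated, up to 20 times,
#' if a character comes out constant at the tips); (3) species trait means by
#' Brownian motion, or with an exact Ornstein-Uhlenbeck transition toward
#' `theta_social` on edges whose child node's true foraging state is social
#' when `convergence` is on; (4) specimen records with per-specimen Gaussian
#' noise and left/right side jitter (bilateral traits), middle tail derived
#' as outer tail minus fork depth; measurements floored at 0.1 mm so records
#' stay physically valid; (5) behaviour records (maximum breeding group size
#' consistent with the true state, foraging category labels).
#'
#' @param config a [synthetic_config()] list.
#' @return object of class `"synthetic_dataset"`: list with `tree`,
#'   `liabilities` (nodes x 2), `states` (list breeding/foraging over all
#'   nodes), `trait_means` (true species means), `specimens`, `behavior`,
#'   `config`.
#' @export
make_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  set.seed(cf$seed)
  tree <- make_yule_tree(cf$n_species, cf$birth_rate)
  height <- max(.node_depths(tree))
  ntip <- length(tree$tip.label)

  # correlated liabilities -> social states, regenerating degenerate draws
  Rliab <- cf$liability_sigma2 * matrix(c(1, cf$rho, cf$rho, 1), 2L)
  for (attempt in seq_len(20L)) {
    liab <- simulate_bm(tree, R = Rliab, root_state = cf$root_liability,
                        n = 1, internal = TRUE)
    states <- liab > 0
    ok <- all(apply(states[seq_len(ntip), , drop = FALSE], 2L,
                    function(s) length(unique(s)) == 2L))
    if (ok) break
    if (attempt == 20L) {
      stop("could not generate non-constant social characters in 20 tries; ",
           "adjust root_liability/liability_sigma2")
    }
  }
  colnames(liab) <- colnames(states) <- c("breeding", "foraging")
  st_breed <- as.integer(states[, "breeding"])
  st_forag <- as.integer(states[, "foraging"])
  names(st_breed) <- names(st_forag) <- rownames(liab)

  # species trait means: BM, or convergent OU on social-foraging lineages
  traits <- names(cf$trait_means)
  sigma2 <- cf$trait_sds^2 / height
  if (cf$convergence && cf$alpha_height > 0) {
    theta <- rbind(solitary = cf$trait_means, social = cf$theta_social)
    edge_reg <- 1L + st_forag[tree$edge[, 2L]]
    mu <- simulate_ou(tree, alpha = cf$alpha_height / height, theta = theta,
                      sigma2 = sigma2, root_state = cf$trait_means,
                      edge_regimes = edge_reg, internal = FALSE)
  } else {
    mu <- simulate_bm(tree, sigma2 = sigma2, root_state = cf$trait_means,
                      internal = FALSE)
  }
  colnames(mu) <- traits

  # specimen records
  nspec <- cf$n_males + cf$n_females
  sex <- c(rep("M", cf$n_males), rep("F", cf$n_females))
  floor_mm <- function(x) pmax(x, 0.1)
  rows <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    v <- matrix(rnorm(nspec * length(traits), mean = rep(mu[i, ], each = nspec),
                      sd = rep(cf$noise_sd, each = nspec)),
                nspec, length(traits), dimnames = list(NULL, traits))
    side <- function(x) floor_mm(x + rnorm(nspec, 0, cf$side_jitter_sd))
    outer_L <- side(v[, "outer_tail"]); outer_R <- side(v[, "outer_tail"])
    rows[[i]] <- data.frame(
      species = tree$tip.label[i], sex = sex,
      wing = floor_mm(v[, "wing"]),
      outer_tail_L = outer_L, outer_tail_R = outer_R,
      middle_tail = floor_mm((outer_L + outer_R) / 2 - v[, "tail_fork"]),
      tarsus_L = side(v[, "tarsus"]), tarsus_R = side(v[, "tarsus"]),
      bill_length = floor_mm(v[, "bill_length"]),
      bill_width = floor_mm(v[, "bill_width"]),
      stringsAsFactors = FALSE
    )
  }
  specimens <- do.call(rbind, rows)

  # behaviour records consistent with the true states
  tips <- seq_len(ntip)
  breed_tip <- st_breed[tips]; forag_tip <- st_forag[tips]
  max_pairs <- ifelse(breed_tip == 1L,
                      pmin(round(5 * exp(rexp(ntip, 1 / 1.5))), 6000),
                      sample(1:4, ntip, replace = TRUE))
  if (cf$n_missing_breeding > 0) {
    drop <- sample.int(ntip, min(cf$n_missing_breeding, ntip - 4L))
    max_pairs[drop] <- NA
  }
  behavior <- data.frame(
    species = tree$tip.label,
    max_breeding_pairs = max_pairs,
    cavity_override = 0L,
    foraging_category = ifelse(forag_tip == 1L, "groups", "pairs"),
    stringsAsFactors = FALSE
  )

  structure(list(
    tree = tree, liabilities = liab,
    states = list(breeding = st_breed, foraging = st_forag),
    trait_means = mu, specimens = specimens, behavior = behavior,
    config = config
  ), class = "synthetic_dataset")
}

#' Write a synthetic dataset as analysis-ready fixture files
#'
#' Emits `tree.nwk`, `specimens.csv`, `behavior.csv` in the formats the
#' readers consume, plus `truth.json` carrying the simulated ground truth
#' (states, liabilities, species means, configuration). All files are plain
#' text.
#'
#' @param dataset a `"synthetic_dataset"`.
#' @param dir output directory (created if needed).
#' @return invisible character vector of file paths.
#' @export
write_fixture <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("tree.nwk", "specimens.csv", "behavior.csv",
                            "truth.json"))
  write_newick(dataset$tree, paths[1L])
  write.csv(dataset$specimens, paths[2L], row.names = FALSE)
  write.csv(dataset$behavior, paths[3L], row.names = FALSE)
  cf <- dataset$config
  truth <- list(
    schema = "socioconv-truth/1",
    states = dataset$states,
    liabilities = as.data.frame(dataset$liabilities),
    node_names = rownames(dataset$liabilities),
    trait_means = as.data.frame(dataset$trait_means),
    species = rownames(dataset$trait_means),
    config = unclass(cf)
  )
  jsonlite::write_json(truth, paths[4L], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
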
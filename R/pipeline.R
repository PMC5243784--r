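# End-to-end orchestration: tree + specimen CSV + behaviour CSV in, a
# structured report out. Each behaviour (breeding, foraging) is analysed on
# its own pruned taxon set: descriptive statistics, per-trait phylogenetic
# t-tests with Holm correction, threshold-model ancestral reconstruction,
# Stayton indices with BM-simulation significance, the Wheatsheaf index with
# permutation significance, and phylomorphospace coordinates. Pagel's test
# relates the two behaviours on their common taxa.

#' Analysis configuration
#'
#' Replicate counts default to full study scale (10,000 t-test simulations,
#' 1,000 convergence simulations, 1,000 Pagel simulations, threshold MCMC of
#' 2,000,000 generations thinned every 2,000 with 10% burn-in). The
#' Wheatsheaf default is 10,000 permutations; `full_perms` raises it to
#' 1,000,000 (Monte-Carlo error of the 10,000-permutation p is about 0.005
#' at p = 0.5, far below any decision threshold used here).
#'
#' @param n_sims_ttest,n_sims_conv,n_sims_pagel,n_perm replicate counts.
#' @param mcmc_gen,mcmc_thin,mcmc_burnin threshold-MCMC settings.
#' @param full_perms use 1,000,000 Wheatsheaf permutations.
#' @param ttest_scale traits fed to the t-tests: `"raw"` mm (default) or
#'   `"scaled"` (tarsus-relative).
#' @param conv_scale traits fed to the convergence metrics: `"scaled"`
#'   (default) or `"raw"`.
#' @param zscore z-scale traits inside the convergence metrics (default
#'   TRUE, so no single trait dominates the Euclidean distances).
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(n_sims_ttest = 10000, n_sims_conv = 1000,
                            n_sims_pagel = 1000, n_perm = 10000,
                            mcmc_gen = 2e6, mcmc_thin = 2000,
                            mcmc_burnin = 0.10, full_perms = FALSE,
                            ttest_scale = c("raw", "scaled"),
                            conv_scale = c("scaled", "raw"),
                            zscore = TRUE, seed = 1) {
  ttest_scale <- match.arg(ttest_scale)
  conv_scale <- match.arg(conv_scale)
  if (full_perms) n_perm <- 1e6
  structure(as.list(environment()), class = "analysis_config")
}

# z-score trait columns (used by the convergence stage)
.zscore_cols <- function(m) {
  s <- apply(m, 2L, stats::sd)
  s[s == 0] <- 1
  sweep(sweep(m, 2L, colMeans(m), "-"), 2L, s, "/")
}

#' Phylomorphospace coordinates
#'
#' Tip points are the observed values of the two chosen axes; internal-node
#' points are their ML Brownian-motion ancestral estimates; edges connect
#' parent to child points. No statistics are computed — this is an
#' exploratory projection.
#'
#' @param tree a `"phylo"` object.
#' @param mat taxa x variables matrix covering every tip.
#' @param x_var,y_var column names of the two axes.
#' @return list with `points` (data.frame: node, label, type, x, y) and
#'   `edges` (data.frame: parent, child, ape node ids).
#' @export
phylomorphospace <- function(tree, mat, x_var, y_var) {
  tree <- validate_phylogeny(tree, warn_zero = FALSE)
  mat <- .tip_matrix(tree, mat)
  for (v in c(x_var, y_var)) {
    if (!v %in% colnames(mat)) stop("no column ", v)
  }
  xy <- mat[, c(x_var, y_var), drop = FALSE]
  all_nodes <- ancestral_ml(tree, xy)
  ntip <- length(tree$tip.label)
  pts <- data.frame(
    node = seq_len(nrow(all_nodes)),
    label = rownames(all_nodes),
    type = rep(c("tip", "node"), c(ntip, tree$Nnode)),
    x = all_nodes[, 1L], y = all_nodes[, 2L],
    row.names = NULL
  )
  list(points = pts,
       edges = data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L]))
}

.stage <- function(report, name, expr) {
  if (!is.null(report$failed_stage)) return(report)
  val <- tryCatch(expr, error = function(e) e)
  if (inherits(val, "error")) {
    report$status <- "partial"
    report$failed_stage <- name
    report$error <- conditionMessage(val)
    warning("stage '", name, "' failed: ", conditionMessage(val))
  } else {
    report[[name]] <- val
  }
  report
}

# analysis of one behaviour on its pruned taxon set
.analyse_behavior <- function(tree, raw, scaled, char, label, cf, seed0) {
  taxa <- intersect(rownames(raw), names(char))
  taxa <- intersect(taxa, tree$tip.label)
  if (length(taxa) < 10L) stop("fewer than 10 taxa for ", label)
  tr <- prune_to(tree, taxa)
  sn <- attr(char, "state_names")
  char <- .binary_character(char[taxa], sn)
  raw <- raw[taxa, , drop = FALSE]
  scaled <- scaled[rownames(scaled) %in% taxa, , drop = FALSE]
  focal <- names(char)[char == 1L]
  conv_traits <- if (cf$conv_scale == "scaled") scaled else raw
  if (cf$zscore) conv_traits <- .zscore_cols(conv_traits)
  ttest_traits <- if (cf$ttest_scale == "raw") raw else scaled

  asr <- ancestral_threshold(tr, char, n_gen = cf$mcmc_gen,
                             sample_every = cf$mcmc_thin,
                             burnin = cf$mcmc_burnin, seed = seed0 + 1L)
  conv <- stayton_significance(tr, conv_traits, focal,
                               n_sims = cf$n_sims_conv, seed = seed0 + 2L)
  wheat <- wheatsheaf_pvalue(tr, conv_traits, focal, n_perm = cf$n_perm,
                             seed = seed0 + 3L)
  ttab <- phylo_ttest_table(tr, ttest_traits, char,
                            n_sims = cf$n_sims_ttest, seed = seed0 + 4L)
  root <- as.character(.root_id(tr))
  list(
    behavior = label, state_names = sn,
    n_taxa = length(taxa),
    n_state0 = sum(char == 0L), n_state1 = sum(char == 1L),
    descriptive_raw = descriptive_stats(raw, char),
    descriptive_scaled = descriptive_stats(scaled, char),
    ttests = ttab,
    threshold_asr = list(post = asr$post, acceptance = asr$acceptance,
                         ess_root = asr$ess_root,
                         split_rhat_root = asr$split_rhat_root,
                         root_p_state1 = unname(asr$post[root])),
    convergence = list(C1 = conv$C1, C2 = conv$C2, C3 = conv$C3,
                       C4 = conv$C4, p = as.list(conv$p),
                       n_sims = conv$n_sims, n_pairs = conv$n_pairs),
    wheatsheaf = list(w = wheat$w, p = wheat$p, n_perm = wheat$n_perm),
    taxa = taxa, focal = focal
  )
}

#' Run the full comparative analysis
#'
#' @param tree_file Newick tree file.
#' @param specimens_file specimen measurement CSV (see
#'   [read_specimen_csv()]).
#' @param behavior_file behaviour CSV (see [read_behavior_csv()]).
#' @param out_dir optional directory; when given, `report.json`, per-behaviour
#'   t-test tables, posterior-state CSVs and phylomorphospace coordinate CSVs
#'   are written there.
#' @param config an [analysis_config()].
#' @return report list (class `"socioconv_report"`); `report$status` is
#'   `"complete"`, or `"partial"` with `failed_stage` naming the stage that
#'   failed.
#' @export
run_analysis <- function(tree_file, specimens_file, behavior_file,
                         out_dir = NULL, config = analysis_config()) {
  cf <- config
  report <- list(status = "complete",
                 package_version = as.character(packageVersion("socioconv")),
                 config = unclass(cf))
  report <- .stage(report, "inputs", {
    tree <- read_phylogeny(tree_file)
    specimens <- read_specimen_csv(specimens_file)
    behavior <- read_behavior_csv(behavior_file)
    list(tree = tree, specimens = specimens, behavior = behavior,
         n_tree_tips = length(tree$tip.label))
  })
  report <- .stage(report, "traits", {
    sm <- species_means(specimen_traits(report$inputs$specimens))
    keep <- rownames(sm)[rowSums(is.na(sm)) == 0L]
    if (length(keep) < nrow(sm)) {
      warning("dropping species with incomplete traits: ",
              paste(setdiff(rownames(sm), keep), collapse = ", "))
    }
    sm <- sm[keep, , drop = FALSE]
    mr <- match_report(report$inputs$tree, rownames(sm))
    raw <- sm[mr$common, , drop = FALSE]
    list(raw = raw, scaled = scale_by_tarsus(raw), match = mr)
  })
  report <- .stage(report, "characters", {
    behavior_characters(report$inputs$behavior)
  })
  for (bh in c("breeding", "foraging")) {
    report <- .stage(report, bh, {
      .analyse_behavior(report$inputs$tree, report$traits$raw,
                        report$traits$scaled, report$characters[[bh]],
                        bh, cf,
                        seed0 = cf$seed + 100L * match(bh, c("breeding",
                                                             "foraging")))
    })
  }
  report <- .stage(report, "pagel", {
    chA <- report$characters$breeding
    chB <- report$characters$foraging
    common <- Reduce(intersect, list(names(chA), names(chB),
                                     report$inputs$tree$tip.label,
                                     rownames(report$traits$raw)))
    tr <- prune_to(report$inputs$tree, common)
    pg <- pagel_correlation(tr, chA[common], chB[common],
                            n_sims = cf$n_sims_pagel, seed = cf$seed + 300L)
    list(ll_indep = pg$ll_indep, ll_dep = pg$ll_dep, LR = pg$LR, p = pg$p,
         n_sims = pg$n_sims, n_taxa = length(common),
         rates_indep = as.list(pg$rates_indep),
         rates_dep = as.list(pg$rates_dep))
  })
  report <- .stage(report, "phylomorphospace", {
    # maximum breeding group size (log10 pairs) against each raw trait
    beh <- report$inputs$behavior
    gs <- setNames(log10(beh$max_breeding_pairs), beh$species)
    gs <- gs[!is.na(gs)]
    taxa <- intersect(names(gs), rownames(report$traits$raw))
    taxa <- intersect(taxa, report$inputs$tree$tip.label)
    tr <- prune_to(report$inputs$tree, taxa)
    mat <- cbind(log10_group_size = gs[taxa],
                 report$traits$raw[taxa, , drop = FALSE])
    lapply(setNames(nm = colnames(report$traits$raw)), function(v) {
      phylomorphospace(tr, mat, "log10_group_size", v)
    })
  })
  class(report) <- "socioconv_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  if (report$status != "complete") {
    warning("analysis incomplete: failed at stage '", report$failed_stage,
            "'")
  }
  report
}

#' Write a report to disk
#'
#' Emits `report.json` (inputs and bulky intermediates removed) plus CSV
#' tables: per-behaviour t-test tables, posterior node-state probabilities,
#' and phylomorphospace coordinates.
#'
#' @param report a `"socioconv_report"`.
#' @param out_dir output directory (created if needed).
#' @return invisible `out_dir`.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (bh in c("breeding", "foraging")) {
    r <- report[[bh]]
    if (is.null(r)) next
    write.csv(r$ttests, file.path(out_dir, paste0("ttests_", bh, ".csv")),
              row.names = FALSE)
    write.csv(data.frame(node = names(r$threshold_asr$post),
                         p_state1 = unname(r$threshold_asr$post)),
              file.path(out_dir, paste0("posterior_", bh, ".csv")),
              row.names = FALSE)
  }
  if (!is.null(report$phylomorphospace)) {
    for (v in names(report$phylomorphospace)) {
      write.csv(report$phylomorphospace[[v]]$points,
                file.path(out_dir, paste0("coords_", v, ".csv")),
                row.names = FALSE)
    }
  }
  slim <- report
  slim$inputs <- NULL
  slim$phylomorphospace <- NULL
  slim$traits <- lapply(report$traits[c("raw", "scaled")], as.data.frame)
  for (bh in c("breeding", "foraging")) {
    if (!is.null(slim[[bh]])) {
      slim[[bh]]$threshold_asr$post <- as.list(slim[[bh]]$threshold_asr$post)
    }
  }
  slim$characters <- lapply(report$characters, function(ch) {
    as.list(setNames(as.integer(ch), names(ch)))
  })
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.socioconv_report <- function(x, ...) {
  cat("socioconv analysis report (status:", x$status, ")\n")
  for (bh in c("breeding", "foraging")) {
    r <- x[[bh]]
    if (is.null(r)) next
    cat(sprintf("%s: %d taxa (%d %s / %d %s)\n", bh, r$n_taxa,
                r$n_state0, r$state_names[1L], r$n_state1, r$state_names[2L]))
    cat(sprintf("  C1 = %.3f (p = %.3g), w = %.3f (p = %.3g), P(root %s) = %.3f\n",
                r$convergence$C1, r$convergence$p$C1, r$wheatsheaf$w,
                r$wheatsheaf$p, r$state_names[2L],
                r$threshold_asr$root_p_state1))
  }
  if (!is.null(x$pagel)) {
    cat(sprintf("Pagel correlation: LR = %.3f, p = %.3g\n",
                x$pagel$LR, x$pagel$p))
  }
  invisible(x)
}
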
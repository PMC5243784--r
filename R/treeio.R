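# Tree input/validation and phylogenetic covariance services.
#
# Trees are ordinary ape "phylo" objects throughout; this file adds strict
# validation (unique non-empty tip labels, branch lengths present and
# non-negative, connectedness), whitespace-trimmed label handling, and the
# covariance/pruning operations downstream code relies on. Polytomies are
# legal everywhere.

#' Validate a phylogeny
#'
#' Checks the structural invariants assumed by every analysis in the package:
#' a single root, exactly one parent per non-root node, unique non-empty tip
#' labels, branch lengths present and non-negative, and connectedness (every
#' node reachable from the root). Zero-length terminal branches are permitted
#' but trigger a warning because they make liability constraints and GLS
#' weights degenerate.
#'
#' @param tree an object of class `"phylo"`.
#' @param warn_zero warn on zero-length terminal branches (default `TRUE`).
#' @return `tree`, invisibly, with tip labels whitespace-trimmed.
#' @export
validate_phylogeny <- function(tree, warn_zero = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have at least 2 tips")
  tree$tip.label <- trimws(tree$tip.label)
  if (any(!nzchar(tree$tip.label))) stop("empty tip label(s)")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length)) stop("branch lengths are required")
  if (anyNA(tree$edge.length)) stop("missing branch length(s)")
  neg <- tree$edge.length < 0
  if (any(neg)) {
    stop("negative branch length(s) on edge(s): ",
         paste(which(neg), collapse = ", "))
  }
  nnode <- tree$Nnode
  nodes <- seq_len(ntip + nnode)
  child <- tree$edge[, 2L]
  if (anyDuplicated(child)) stop("node with more than one parent")
  root <- setdiff(nodes, child)
  if (length(root) != 1L) stop("tree must have exactly one root")
  # connectedness: every node except the root appears as a child
  if (length(child) != ntip + nnode - 1L) stop("tree is not connected")
  if (warn_zero) {
    term0 <- tree$edge.length == 0 & child <= ntip
    if (any(term0)) {
      warning("zero-length terminal branch(es) for tip(s): ",
              paste(tree$tip.label[child[term0]], collapse = ", "))
    }
  }
  invisible(tree)
}

#' Parse a Newick string into a validated phylogeny
#'
#' Thin, strict wrapper around [ape::read.tree()]: branch lengths are
#' mandatory, tip labels must be unique and non-empty after trimming
#' surrounding whitespace, and negative branch lengths are an error.
#'
#' @param text a single Newick string (terminated by `;`).
#' @return a validated `"phylo"` object.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick string: ", substr(text, 1L, 60L))
  }
  tree <- suppressWarnings(validate_phylogeny(tree, warn_zero = FALSE))
  tree
}

#' Read a phylogeny from a Newick file
#' @param path path to a Newick file containing one tree.
#' @return a validated `"phylo"` object.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Write a phylogeny in Newick format
#' @param tree a `"phylo"` object.
#' @param path optional output file; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Prune a phylogeny down to a set of tips
#'
#' Keeps exactly the requested taxa; internal nodes left with a single child
#' are suppressed with their branch lengths summed, so every kept tip retains
#' its original root-to-tip path length (and every pairwise tip path length is
#' preserved).
#'
#' @param tree a `"phylo"` object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `"phylo"` object.
#' @export
prune_to <- function(tree, keep) {
  tree <- suppressWarnings(validate_phylogeny(tree, warn_zero = FALSE))
  keep <- trimws(keep)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  }
  if (length(unique(keep)) < 2L) stop("need at least 2 tips to keep")
  ape::keep.tip(tree, keep)
}

#' Phylogenetic variance-covariance structure
#'
#' Entry (i, j) is the branch length shared by the root-to-tip paths of taxa
#' i and j (their most recent common ancestor's depth); the diagonal holds
#' root-to-tip depths. This is the covariance structure Brownian motion
#' induces on tip values, up to the rate.
#'
#' @param tree a `"phylo"` object.
#' @return a symmetric positive semidefinite matrix with tip labels as
#'   dimnames, rows/columns in `tree$tip.label` order.
#' @export
phylo_vcv <- function(tree) {
  tree <- suppressWarnings(validate_phylogeny(tree, warn_zero = FALSE))
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Report label agreement between a tree and a data table
#'
#' Exact, case-sensitive matching after trimming surrounding whitespace.
#' Always emits a message summarising the mismatch so silent taxon loss is
#' impossible.
#'
#' @param tree a `"phylo"` object.
#' @param taxa character vector of table taxa.
#' @return list with `common`, `tree_only`, `table_only`.
#' @export
match_report <- function(tree, taxa) {
  taxa <- trimws(taxa)
  rep <- list(
    common     = intersect(tree$tip.label, taxa),
    tree_only  = setdiff(tree$tip.label, taxa),
    table_only = setdiff(taxa, tree$tip.label)
  )
  message(sprintf("label match: %d common, %d tree-only, %d table-only",
                  length(rep$common), length(rep$tree_only),
                  length(rep$table_only)))
  rep
}

# ---- internal tree services -------------------------------------------------

# parent id per node (0 for root), in ape node numbering
.parent_vec <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  par <- integer(n)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

# branch length leading to each node (0 for root)
.blen_vec <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  bl <- numeric(n)
  bl[tree$edge[, 2L]] <- tree$edge.length
  bl
}

.root_id <- function(tree) {
  setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
}

# depth (distance from root) of every node
.node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

# nodes on the path from `node` up to and including `stop_at`
.path_to <- function(parent, node, stop_at) {
  path <- node
  while (node != stop_at) {
    node <- parent[node]
    if (node == 0L) stop("stop_at is not an ancestor of node")
    path <- c(path, node)
  }
  path
}

# edges of the tree in preorder (root first): matrix anc, desc, length
.preorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  cbind(tr$edge, tr$edge.length)
}

.postorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  cbind(tr$edge, tr$edge.length)
}
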
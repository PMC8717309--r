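#' Read and validate a newick phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces what the downstream
#' mixed model needs: a rooted tree, unique tip labels, and branch lengths
#' present and non-negative.
#'
#' @param source Newick string, or path to a newick file.
#' @param missing_lengths `"error"` (default) or `"zero"` to replace absent
#'   branch lengths by 0.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(source, missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  tr <- if (file.exists(source)) {
    tryCatch(ape::read.tree(source), error = function(e) NULL)
  } else {
    tryCatch(ape::read.tree(text = source), error = function(e) NULL)
  }
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop_invalid("Malformed newick input.", class = "endolink_parse_error")
  }
  if (anyDuplicated(tr$tip.label)) {
    stop_invalid("Duplicate tip labels.", class = "endolink_parse_error")
  }
  if (is.null(tr$edge.length)) {
    if (missing_lengths == "error") {
      stop_invalid("Tree has no branch lengths.", class = "endolink_parse_error")
    }
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length) || any(tr$edge.length < 0)) {
    stop_invalid("Branch lengths must be present and non-negative.",
                 class = "endolink_parse_error")
  }
  tr
}

#' Phylogenetic variance-covariance matrix
#'
#' Brownian-motion covariance implied by a rooted tree: entry (i, j) is the
#' total branch length shared by the root-to-tip paths of tips i and j; the
#' diagonal holds root-to-tip depths. Zero-depth terminal branches are
#' nudged by `epsilon` (a fraction of the maximum depth) so the matrix
#' stays invertible for the sampler.
#'
#' @param tree An [ape::phylo] tree (rooted).
#' @param epsilon Relative nudge added to zero diagonal entries
#'   (default 1e-8 of tree depth).
#' @return Symmetric matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree, epsilon = 1e-8) {
  if (!inherits(tree, "phylo")) stop_invalid("`tree` must be a phylo object.")
  # an unrooted binary tree (the usual ML output) has Ntip - 2 internal
  # nodes; genuine multifurcating stars have fewer and are accepted
  if (!ape::is.rooted(tree) &&
        tree$Nnode == length(tree$tip.label) - 2) {
    stop_invalid("Tree is unrooted; root it first (midpoint or outgroup).",
                 class = "endolink_unrooted")
  }
  C <- ape::vcv.phylo(tree)
  # a retained root edge (e.g. after pruning) is ancestry shared by all tips
  if (isTRUE(is.finite(tree$root.edge) && tree$root.edge > 0)) {
    C <- C + tree$root.edge
  }
  depth <- max(diag(C))
  if (depth <= 0) stop_invalid("Tree has zero total depth.")
  zero <- diag(C) <= 0
  if (any(zero)) diag(C)[zero] <- epsilon * depth
  C
}

#' Standardize a phylogenetic covariance to a correlation matrix
#'
#' @param C Phylogenetic covariance matrix with positive diagonal.
#' @return Correlation matrix with unit diagonal.
#' @export
vcv_to_correlation <- function(C) {
  if (any(diag(C) <= 0)) {
    stop_invalid("Zero-depth tip: covariance diagonal must be positive.")
  }
  stats::cov2cor(C)
}

#' Prune a tree to a species set and map tips to rows
#'
#' Restricts the tree to the requested species (internal branches are
#' coalesced) and returns the index mapping from the pruned tip order into
#' the request order. Matching uses the package-wide name normalization
#' (case-insensitive, spaces/underscores unified); unmatched species are an
#' error, never fuzzy-matched.
#'
#' @param tree An [ape::phylo] tree.
#' @param species Character vector of species names to keep.
#' @return List with `tree` (pruned), `index` (integer vector: for each
#'   entry of `species`, the position of its tip in `tree$tip.label`).
#' @export
prune_to_species <- function(tree, species) {
  tip_norm <- normalize_species(tree$tip.label)
  want <- normalize_species(species)
  missing_sp <- species[!want %in% tip_norm]
  if (length(missing_sp)) {
    stop_invalid(paste0("Species not in tree: ",
                        paste(missing_sp, collapse = ", ")))
  }
  keep <- tree$tip.label[tip_norm %in% want]
  pruned <- if (length(keep) < length(tree$tip.label)) {
    pr <- ape::keep.tip(tree, keep)
    # record the path between the old root and the retained clade's MRCA as
    # a root edge, so root-to-tip depths (hence the covariance) survive
    old_depth <- ape::node.depth.edgelength(tree)[match(keep[1],
                                                        tree$tip.label)]
    new_depth <- ape::node.depth.edgelength(pr)[match(keep[1], pr$tip.label)]
    lost <- old_depth - new_depth
    if (lost > 1e-12) {
      pr$root.edge <- lost + if (is.null(pr$root.edge)) 0 else pr$root.edge
    }
    pr
  } else tree
  idx <- match(want, normalize_species(pruned$tip.label))
  list(tree = pruned, index = idx)
}
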
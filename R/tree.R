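#' Read a rooted phylogeny from a Newick file
#'
#' Thin validated wrapper around [ape::read.tree()]: requires unique leaf
#' labels, at least two leaves, and branch lengths on every edge. Polytomies
#' are allowed; zero-length branches trigger a warning.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse failure: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse failure: no tree in ", path)
  validate_phylogeny(tree)
}

#' Validate a phylogeny for comparative analysis
#'
#' @param tree An [ape::phylo] object.
#' @return The tree, invisibly unchanged, or an error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (length(tree$tip.label) < 2L) stop("phylogeny needs at least 2 leaves")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label)))
    stop("unlabeled leaves in phylogeny")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop("phylogeny is missing branch lengths")
  if (any(is.na(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be nonnegative and complete")
  if (any(tree$edge.length == 0))
    warning("phylogeny contains zero-length branches")
  tree
}

#' Normalize species names for cross-source matching
#'
#' Case-folds and converts spaces to underscores so that e.g. "Homo sapiens"
#' and "homo_sapiens" match.
#'
#' @param x Character vector of species names.
#' @return Normalized names.
#' @export
normalize_species <- function(x) {
  gsub("\\s+", "_", tolower(trimws(x)))
}

#' Restrict a tree and trait table to their shared species
#'
#' Matches tree leaves to trait-table rows after name normalization, prunes
#' the tree to the intersection (internal path lengths among retained taxa
#' are preserved), and reorders the trait rows to tip order.
#'
#' @param tree An [ape::phylo] object.
#' @param traits A `data.frame` with a `species_id` column.
#' @return A list with elements `tree`, `traits` (rows in `tree$tip.label`
#'   order), `dropped_from_tree` and `dropped_from_traits` (original names).
#' @export
prune_and_match <- function(tree, traits) {
  validate_phylogeny(tree)
  stopifnot(is.data.frame(traits), "species_id" %in% names(traits))
  tip_norm <- normalize_species(tree$tip.label)
  trait_norm <- normalize_species(traits$species_id)
  if (anyDuplicated(trait_norm))
    stop("duplicate species in trait table after name normalization")
  keep_norm <- intersect(tip_norm, trait_norm)
  if (!length(keep_norm))
    stop("no species shared between tree and trait table")
  dropped_tips <- tree$tip.label[!tip_norm %in% keep_norm]
  dropped_rows <- traits$species_id[!trait_norm %in% keep_norm]
  if (length(dropped_tips))
    message("prune_and_match: dropping ", length(dropped_tips),
            " tree leaves without traits")
  if (length(dropped_rows))
    message("prune_and_match: dropping ", length(dropped_rows),
            " trait rows without tree leaves")
  if (length(dropped_tips)) {
    # keep the collapsed root path as a root edge so that root-to-MRCA path
    # lengths among retained taxa (hence the Brownian VCV) are unchanged
    old_depth <- .tip_depths(tree)
    pruned <- ape::drop.tip(tree, dropped_tips)
    probe <- pruned$tip.label[1]
    offset <- unname(old_depth[probe] - .tip_depths(pruned)[probe])
    old_root <- if (is.null(tree$root.edge) || is.na(tree$root.edge)) 0
                else tree$root.edge
    pruned$root.edge <- old_root + max(0, offset)
    tree <- pruned
  }
  ord <- match(normalize_species(tree$tip.label), trait_norm)
  traits <- traits[ord, , drop = FALSE]
  traits$species_id <- tree$tip.label   # adopt tree spelling
  rownames(traits) <- NULL
  list(tree = tree, traits = traits,
       dropped_from_tree = dropped_tips,
       dropped_from_traits = dropped_rows)
}

# root-to-tip path lengths (excluding any root edge), named by tip label
.tip_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  depth <- numeric(n_tip + tree$Nnode)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tr$edge)))
    depth[tr$edge[k, 2L]] <- depth[tr$edge[k, 1L]] + tr$edge.length[k]
  stats::setNames(depth[seq_len(n_tip)], tree$tip.label)
}

#' Brownian-motion variance-covariance matrix of a phylogeny
#'
#' Builds the expected trait covariance matrix under Brownian evolution:
#' entry (i, j) is the path length from the root to the most recent common
#' ancestor of taxa i and j, so diagonals are root-to-tip distances.
#' Computed from the edge list by accumulating node depths and reading the
#' depth of each pair's MRCA.
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @param taxa Ordered character vector of leaf names to include (default all
#'   tips in tree order).
#' @return Symmetric numeric matrix with `taxa` as dim names.
#' @export
brownian_vcv <- function(tree, taxa = tree$tip.label) {
  validate_phylogeny(tree)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  # node depths: root has depth 0; children add their branch length
  depth <- numeric(n_node)
  root <- n_tip + 1L
  # edges in ape cladewise order are parent-before-child from the root
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tr$edge))) {
    depth[tr$edge[k, 2L]] <- depth[tr$edge[k, 1L]] + tr$edge.length[k]
  }
  idx <- match(taxa, tree$tip.label)
  mrca_nodes <- if (length(idx) > 1L) ape::mrca(tree)[idx, idx, drop = FALSE]
                else matrix(root, 1L, 1L)
  C <- matrix(depth[mrca_nodes], nrow = length(idx))
  diag(C) <- depth[idx]
  # a root edge is shared ancestry of every taxon (it arises when pruning
  # collapses the original root); it adds to every covariance entry
  if (!is.null(tree$root.edge) && !is.na(tree$root.edge) && tree$root.edge > 0)
    C <- C + tree$root.edge
  dimnames(C) <- list(taxa, taxa)
  C
}
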
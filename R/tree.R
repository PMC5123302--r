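#' Species tree with a marked ancestor
#'
#' Wraps a rooted binary phylogeny (an \code{ape} \code{phylo} object) together
#' with the internal node at which the ancestral genome is to be
#' reconstructed.  Branches without lengths are assigned length 1.
#'
#' @param phylo an \code{ape::phylo} object, rooted and binary.
#' @param ancestor label (or internal node number) of the marked ancestor.
#' @return an object of class \code{multires_tree}: a list with elements
#'   \code{phylo} (the tree), \code{ancestor} (internal node number) and
#'   \code{ancestor_label}.
#' @export
species_tree <- function(phylo, ancestor) {
  if (!inherits(phylo, "phylo")) stop("'phylo' must be an ape phylo object")
  if (!ape::is.rooted(phylo)) stop("tree must be rooted")
  if (!ape::is.binary(phylo)) stop("tree must be binary")
  if (anyDuplicated(phylo$tip.label)) stop("leaf labels must be distinct")
  if (is.null(phylo$edge.length)) {
    phylo$edge.length <- rep(1, nrow(phylo$edge))
  }
  phylo$edge.length[is.na(phylo$edge.length)] <- 1
  ntip <- length(phylo$tip.label)
  if (is.character(ancestor)) {
    if (is.null(phylo$node.label)) stop("tree has no internal node labels")
    idx <- match(ancestor, phylo$node.label)
    if (is.na(idx)) stop(sprintf("no internal node labelled '%s'", ancestor))
    anc <- ntip + idx
    anc_label <- ancestor
  } else {
    anc <- as.integer(ancestor)
    if (anc <= ntip || anc > ntip + phylo$Nnode) stop("ancestor is not an internal node")
    anc_label <- if (!is.null(phylo$node.label)) phylo$node.label[anc - ntip] else as.character(anc)
  }
  structure(list(phylo = phylo, ancestor = anc, ancestor_label = anc_label),
            class = "multires_tree")
}

#' Read a species tree from a newick file
#'
#' The marked ancestor is identified by its internal node label.  Missing
#' branch lengths default to 1.
#'
#' @param path newick file.
#' @param ancestor internal node label of the marked ancestor.
#' @return a \code{multires_tree}.
#' @export
read_tree <- function(path, ancestor) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse newick file: ", path)
  species_tree(phy, ancestor)
}

tree_leaves <- function(tree) tree$phylo$tip.label

#' Does the marked ancestor lie on the path between two species?
#'
#' @param tree a \code{multires_tree}.
#' @param s_a,s_b leaf labels.  The path between a leaf and itself is empty,
#'   so \code{ancestor_on_path(tree, s, s)} is \code{FALSE}.
#' @return logical.
#' @export
ancestor_on_path <- function(tree, s_a, s_b) {
  phy <- tree$phylo
  ia <- match(s_a, phy$tip.label)
  ib <- match(s_b, phy$tip.label)
  if (is.na(ia) || is.na(ib)) stop("unknown leaf label")
  if (ia == ib) return(FALSE)
  path <- ape::nodepath(phy, ia, ib)
  tree$ancestor %in% path
}

# All unordered leaf pairs whose path passes through the marked ancestor.
# Returns a 2-column character matrix.
straddling_pairs <- function(tree) {
  lv <- tree_leaves(tree)
  n <- length(lv)
  out <- matrix(character(0), ncol = 2)
  if (n < 2) return(out)
  cmb <- utils::combn(n, 2)
  keep <- vapply(seq_len(ncol(cmb)), function(j) {
    ancestor_on_path(tree, lv[cmb[1, j]], lv[cmb[2, j]])
  }, logical(1))
  cbind(lv[cmb[1, keep]], lv[cmb[2, keep]])
}

# Patristic distances between leaves, as a named matrix.
leaf_distances <- function(tree) {
  stats::cophenetic(tree$phylo)
}

#' @export
print.multires_tree <- function(x, ...) {
  cat(sprintf("Species tree: %d leaves, marked ancestor '%s'\n",
              length(tree_leaves(x)), x$ancestor_label))
  invisible(x)
}
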
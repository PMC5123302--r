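# Parsimoniously conserved adjacencies, their phylogenetic weights, and
# ancestral copy numbers.

# Per-species sets of adjacency keys observed in the doubled gene orders.
# genes: data.frame (species, chrom, start, end, sign, family), sorted.
species_adjacency_sets <- function(genes) {
  out <- list()
  for (sp in unique(genes$species)) {
    gs <- genes[genes$species == sp, ]
    keys <- unlist(lapply(split(gs, gs$chrom), function(chr) {
      chr <- chr[order(chr$start), ]
      chromosome_adjacencies(double_gene_order(chr$family, chr$sign))
    }), use.names = FALSE)
    out[[sp]] <- unique(keys)
  }
  out
}

# Logical matrix over species: does the marked ancestor lie on the path?
straddle_matrix <- function(tree, species) {
  n <- length(species)
  m <- matrix(FALSE, n, n, dimnames = list(species, species))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- ancestor_on_path(tree, species[i], species[j])
    }
  }
  m
}

#' Parsimoniously conserved adjacencies
#'
#' An adjacency between two markers is conserved in the ancestor if two
#' extant species exhibit it and the marked ancestor lies on the tree path
#' between them.
#'
#' @param genes gene-order data.frame (see \code{\link{read_gene_orders}}).
#' @param tree a \code{multires_tree}.
#' @return list with elements \code{edges} (character vector of canonical
#'   adjacency keys) and \code{evidence} (named list; per edge, a 2-column
#'   character matrix of supporting straddling species pairs).
#' @export
conserved_adjacencies <- function(genes, tree) {
  adj_sets <- species_adjacency_sets(genes)
  species <- names(adj_sets)
  smat <- straddle_matrix(tree, species)
  # adjacency key -> species exhibiting it
  sp_of <- split(rep(species, lengths(adj_sets)),
                 unlist(adj_sets, use.names = FALSE))
  edges <- character(0)
  evidence <- list()
  for (key in names(sp_of)) {
    sps <- sp_of[[key]]
    if (length(sps) < 2) next
    sub <- smat[sps, sps, drop = FALSE]
    idx <- which(upper.tri(sub) & sub, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    edges <- c(edges, key)
    evidence[[key]] <- cbind(sps[idx[, 1]], sps[idx[, 2]])
  }
  list(edges = edges, evidence = evidence)
}

#' Phylogenetic weight of a conserved adjacency
#'
#' Two schemes are provided.  \code{"pair-count"} (default): the number of
#' distinct straddling species pairs supporting the adjacency, divided by
#' the total number of straddling leaf pairs in the tree.
#' \code{"branch-decay"}: the maximum over supporting pairs of
#' \code{exp(-d)}, with \code{d} the patristic distance between the pair.
#' Both are strictly positive for non-empty evidence.
#'
#' @param evidence 2-column matrix of supporting species pairs.
#' @param tree a \code{multires_tree}.
#' @param scheme \code{"pair-count"} or \code{"branch-decay"}.
#' @return positive numeric weight.
#' @export
adjacency_weight <- function(evidence, tree, scheme = c("pair-count", "branch-decay")) {
  scheme <- match.arg(scheme)
  if (is.null(dim(evidence)) || nrow(evidence) == 0) stop("empty evidence")
  if (scheme == "pair-count") {
    total <- nrow(straddling_pairs(tree))
    nrow(unique(evidence)) / total
  } else {
    d <- leaf_distances(tree)
    max(exp(-d[cbind(evidence[, 1], evidence[, 2])]))
  }
}

#' Ancestral copy number by integer small parsimony
#'
#' Leaves are labelled with observed per-species copy counts and an integer
#' Sankoff recursion with per-branch cost \code{|delta| * branch_length} is
#' solved exactly; the value at the marked ancestor minimising the total
#' tree cost is returned (ties broken towards the smallest count).
#'
#' @param counts named integer vector of copy counts per leaf; leaves not
#'   named are taken as 0.
#' @param tree a \code{multires_tree}.
#' @return non-negative integer copy number at the marked ancestor.
#' @export
ancestral_copy_number <- function(counts, tree) {
  leaves <- tree_leaves(tree)
  cc <- stats::setNames(rep(0L, length(leaves)), leaves)
  if (length(counts)) {
    unknown <- setdiff(names(counts), leaves)
    if (length(unknown)) stop("unknown leaf in counts: ", paste(unknown, collapse = ", "))
    cc[names(counts)] <- as.integer(counts)
  }
  if (all(cc == 0)) stop("family absent from all leaves")
  K <- max(cc)
  states <- 0:K
  phy <- tree$phylo
  ntip <- length(leaves)
  nnode <- ntip + phy$Nnode
  # undirected adjacency list with branch lengths
  nb <- vector("list", nnode)
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1]; b <- phy$edge[e, 2]; len <- phy$edge.length[e]
    nb[[a]] <- rbind(nb[[a]], c(b, len))
    nb[[b]] <- rbind(nb[[b]], c(a, len))
  }
  # msg(u -> v): min over label of u of (|cu - cv| * len + sum of messages
  # into u from its other neighbours)
  msg <- function(u, v, len) {
    if (u <= ntip) {
      return(abs(cc[u] - states) * len)
    }
    inner <- rep(0, length(states))
    for (r in seq_len(nrow(nb[[u]]))) {
      w <- nb[[u]][r, 1]
      if (w == v) next
      inner <- inner + msg(w, u, nb[[u]][r, 2])
    }
    vapply(states, function(cv) min(inner + abs(states - cv) * len), numeric(1))
  }
  total <- rep(0, length(states))
  for (r in seq_len(nrow(nb[[tree$ancestor]]))) {
    total <- total + msg(nb[[tree$ancestor]][r, 1], tree$ancestor,
                         nb[[tree$ancestor]][r, 2])
  }
  states[which.min(total)]  # which.min returns the first (smallest) minimiser
}

# Copy counts per leaf for one family from the gene-order table.
leaf_counts <- function(genes, family) {
  tab <- table(genes$species[genes$family == family])
  stats::setNames(as.integer(tab), names(tab))
}

# Ancestral copy numbers for every family in the gene table.
ancestral_copy_numbers <- function(genes, tree) {
  fams <- sort(unique(genes$family))
  vapply(fams, function(f) ancestral_copy_number(leaf_counts(genes, f), tree),
         integer(1))
}

#' Discard gene families with excessive inferred ancestral content
#'
#' Families whose ancestral copy number exceeds \code{cap} are removed from
#' the gene-order table (default cap 15; the boundary is strict, so a
#' family with exactly \code{cap} copies is kept).
#'
#' @param genes gene-order data.frame.
#' @param mu named integer vector of ancestral copy numbers per family.
#' @param cap maximum allowed ancestral copy number.
#' @return filtered gene-order data.frame.
#' @export
filter_families <- function(genes, mu, cap = 15) {
  if (is.infinite(cap)) return(genes)
  drop <- names(mu)[mu > cap]
  out <- genes[!(genes$family %in% drop), ]
  rownames(out) <- NULL
  out
}

#' Build the marker-level ancestral adjacency graph
#'
#' Vertices are the head/tail markers of the surviving families; edges are
#' the conserved adjacencies (weighted) plus the pairing edges between the
#' two markers of each family, flagged separately.
#'
#' @param conserved result of \code{\link{conserved_adjacencies}}.
#' @param mu named integer vector of ancestral copy numbers per family.
#' @param tree a \code{multires_tree}.
#' @param scheme weight scheme, see \code{\link{adjacency_weight}}.
#' @return object of class \code{adjacency_graph}: list with \code{edges}
#'   (data.frame key, u, v, weight, type) and \code{mu}.
#' @export
build_marker_adjacency_graph <- function(conserved, mu, tree,
                                         scheme = "pair-count") {
  keys <- conserved$edges
  keep <- vapply(keys, function(k) {
    ends <- strsplit(k, "--", fixed = TRUE)[[1]]
    all(marker_id(ends) %in% names(mu))
  }, logical(1))
  keys <- keys[keep]
  w <- vapply(keys, function(k) adjacency_weight(conserved$evidence[[k]], tree, scheme),
              numeric(1))
  ends <- strsplit(keys, "--", fixed = TRUE)
  adj <- data.frame(key = keys,
                    u = vapply(ends, `[`, character(1), 1),
                    v = vapply(ends, `[`, character(1), 2),
                    weight = as.numeric(w),
                    type = rep("adjacency", length(keys)))
  fams <- names(mu)[mu > 0]
  pairing <- data.frame(key = pair_key(marker_key(fams, "h"), marker_key(fams, "t")),
                        u = marker_key(fams, "h"), v = marker_key(fams, "t"),
                        weight = 0, type = "pairing")
  structure(list(edges = rbind(adj, pairing), mu = mu),
            class = "adjacency_graph")
}
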
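# Independent brute-force oracles used to pin the combinatorial routines.

# Exhaustive maximum-weight degree-constrained edge subset.  edges: data
# frame (key, u, v, weight) over marker-end vertices; mu_loc: named copy
# numbers per localization.  Enumerates all 2^m subsets at once via an
# incidence-matrix product.
oracle_bmatching_weight <- function(edges, mu_loc) {
  m <- nrow(edges)
  if (m == 0) return(0)
  stopifnot(m <= 14)
  cap_of <- function(end) {
    v <- mu_loc[sub(":[ht]$", "", end)]
    ifelse(is.na(v), 0L, as.integer(v))
  }
  ends <- unique(c(edges$u, edges$v))
  caps <- vapply(ends, cap_of, integer(1))
  # incidence: rows = edges, cols = ends (self-loops count twice)
  M <- matrix(0L, nrow = m, ncol = length(ends), dimnames = list(NULL, ends))
  for (i in seq_len(m)) {
    M[i, edges$u[i]] <- M[i, edges$u[i]] + 1L
    M[i, edges$v[i]] <- M[i, edges$v[i]] + 1L
  }
  S <- as.matrix(do.call(expand.grid, rep(list(0:1), m)))  # 2^m x m
  D <- S %*% M
  feas <- rowSums(D > rep(caps, each = nrow(D))) == 0
  max(c(0, (S %*% edges$weight)[feas]))
}

# Exhaustive integer small parsimony: minimise sum over branches of
# |c_parent - c_child| * length over all labelings of internal nodes with
# states 0..K; returns the smallest optimal state at the marked ancestor.
# Vectorised over labelings (evaluated in chunks to bound memory).
oracle_ancestral_count <- function(counts, tree) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  cc <- stats::setNames(rep(0L, ntip), phy$tip.label)
  cc[names(counts)] <- as.integer(counts)
  K <- max(cc)
  nstates <- K + 1L
  nint <- phy$Nnode
  total <- nstates^nint
  best_cost <- Inf
  best_state <- NA_integer_
  chunk <- 200000L
  for (off in seq(0, total - 1, by = chunk)) {
    idx <- off:min(off + chunk - 1, total - 1)
    # decode mixed-radix labelings: column j is the state of internal node j
    lab <- matrix(0L, nrow = length(idx), ncol = ntip + nint)
    lab[, seq_len(ntip)] <- rep(cc, each = length(idx))
    rem <- idx
    for (j in seq_len(nint)) {
      lab[, ntip + j] <- as.integer(rem %% nstates)
      rem <- rem %/% nstates
    }
    cost <- numeric(length(idx))
    for (e in seq_len(nrow(phy$edge))) {
      cost <- cost + abs(lab[, phy$edge[e, 1]] - lab[, phy$edge[e, 2]]) *
        phy$edge.length[e]
    }
    anc <- lab[, tree$ancestor]
    ord <- order(cost, anc)
    if (cost[ord[1]] < best_cost - 1e-12 ||
        (abs(cost[ord[1]] - best_cost) <= 1e-12 && anc[ord[1]] < best_state)) {
      best_cost <- cost[ord[1]]
      best_state <- anc[ord[1]]
    }
  }
  best_state
}

# random small adjacency-selection instance over a few localizations
random_bmatch_instance <- function(n_loc = 4, n_edges = 8, mu_max = 3) {
  locs <- paste0("f", seq_len(n_loc), "@1")
  mu <- stats::setNames(sample.int(mu_max, n_loc, replace = TRUE), locs)
  ends <- as.vector(outer(locs, c("h", "t"), paste, sep = ":"))
  u <- sample(ends, n_edges, replace = TRUE)
  v <- sample(ends, n_edges, replace = TRUE)
  w <- round(stats::runif(n_edges, 0.1, 1), 3)
  key <- paste(pmin(u, v), pmax(u, v), sep = "--")
  df <- data.frame(key = key, u = u, v = v, weight = w)
  df <- df[!duplicated(df$key), , drop = FALSE]
  list(edges = df, mu = mu)
}
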
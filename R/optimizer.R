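# Per-segment maximum-weight adjacency selection.
#
# Within each CAR segment we select a maximum-total-weight subset of the
# localized adjacencies such that every marker end (head or tail) of a
# localization v is incident to at most mu(v) selected adjacencies -- a
# maximum-weight b-matching on the marker-end graph.  The solver is an
# exact branch-and-bound over edges ordered by decreasing weight, with a
# running upper bound from suffix weight sums; conflict-free connected
# components are taken whole without search.  Among equal-weight optima the
# solution whose sorted edge-identifier ranks are lexicographically
# smallest is returned, so results are independent of input order.

#' Enumerate segments on a CAR
#'
#' Sliding runs of \code{L} consecutive extremities at the given stride
#' (default \code{floor(L / 2)}, so interior regions are covered by at
#' least two segments); the final segment is anchored at the CAR end.  A
#' CAR shorter than \code{L} yields a single whole-CAR segment.
#'
#' @param ext extremity sequence of one CAR.
#' @param L segment length in extremities.
#' @param stride stride in extremities.
#' @return list of segments: each a list with \code{start} and
#'   \code{regions} (spanned region keys).
#' @export
enumerate_segments <- function(ext, L, stride = max(1L, L %/% 2L)) {
  if (stride < 1) stop("stride must be >= 1")
  n <- length(ext)
  rs <- car_region_sequence(ext)
  if (L >= n) {
    return(list(list(start = 1L, regions = rs)))
  }
  starts <- as.integer(seq(1L, n - L + 1L, by = stride))
  if (starts[length(starts)] != n - L + 1L) starts <- c(starts, as.integer(n - L + 1L))
  lapply(starts, function(i) list(start = i, regions = rs[i:(i + L - 2)]))
}

# psi inverse: region key -> localization keys associated with it
psi_inverse <- function(psi) {
  if (length(psi) == 0) return(list())
  inv <- split(rep(names(psi), lengths(psi)), unlist(psi, use.names = FALSE))
  lapply(inv, unique)
}

#' Induced subgraph of the localized adjacency graph on a segment
#'
#' The vertex set is the union of the localizations associated with the
#' segment's regions; edges are those with both endpoint localizations in
#' that set, with copy numbers restricted accordingly.
#'
#' @param edges localized adjacency edge data.frame (key, u, v, weight).
#' @param segment a segment from \code{\link{enumerate_segments}}.
#' @param psi_inv region -> localization map from \code{psi_inverse}.
#' @param mu_loc named integer copy numbers per localization.
#' @return list with \code{vertices} (localization keys), \code{edges} and
#'   \code{mu}.
#' @export
induced_subgraph <- function(edges, segment, psi_inv, mu_loc) {
  vs <- unique(unlist(psi_inv[segment$regions], use.names = FALSE))
  vs <- vs[!is.na(vs)]
  sub <- edges[loc_family_of_end(edges$u) %in% vs &
                 loc_family_of_end(edges$v) %in% vs, , drop = FALSE]
  list(vertices = vs, edges = sub, mu = mu_loc[intersect(names(mu_loc), vs)])
}

#' Maximum-weight degree-constrained adjacency selection
#'
#' Exact maximum-weight b-matching on the marker-end graph: each marker end
#' of localization \code{v} may be incident to at most \code{mu(v)}
#' selected adjacencies.
#'
#' @param edges data.frame (key, u, v, weight) with positive weights;
#'   \code{u}, \code{v} are localization marker-end keys.
#' @param mu_loc named integer copy numbers per localization.
#' @return list with \code{selected} (edge keys), \code{weight} (total).
#' @export
select_adjacencies <- function(edges, mu_loc) {
  if (is.null(edges) || nrow(edges) == 0) {
    return(list(selected = character(0), weight = 0))
  }
  if (any(edges$weight <= 0)) stop("edge weights must be positive")
  cap_of <- function(end) {
    m <- mu_loc[loc_family_of_end(end)]
    ifelse(is.na(m), 0L, as.integer(m))
  }
  feasible <- cap_of(edges$u) > 0 & cap_of(edges$v) > 0 &
    !(edges$u == edges$v & cap_of(edges$u) < 2)
  edges <- edges[feasible, , drop = FALSE]
  if (nrow(edges) == 0) return(list(selected = character(0), weight = 0))
  # canonical order: weight desc, then key asc
  edges <- edges[order(-edges$weight, edges$key), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("u", "v")], directed = FALSE)
  comp <- igraph::components(g)$membership
  ecomp <- comp[edges$u]
  selected <- character(0)
  total <- 0
  for (ci in unique(ecomp)) {
    sub <- edges[ecomp == ci, , drop = FALSE]
    # degree check: component without any capacity conflict is taken whole
    ends <- c(sub$u, sub$v)
    degs <- table(ends)
    caps <- vapply(names(degs), cap_of, integer(1))
    if (all(as.integer(degs) <= caps)) {
      selected <- c(selected, sub$key)
      total <- total + sum(sub$weight)
    } else {
      sol <- bmatch_branch_bound(sub, cap_of)
      selected <- c(selected, sol$selected)
      total <- total + sol$weight
    }
  }
  list(selected = sort(selected), weight = total)
}

# Exact branch and bound on one component.  sub is ordered by
# (weight desc, key asc); rank order doubles as the tie-break preference.
bmatch_branch_bound <- function(sub, cap_of) {
  m <- nrow(sub)
  w <- sub$weight
  u <- sub$u
  v <- sub$v
  suffix <- rev(cumsum(rev(w)))
  ends <- unique(c(u, v))
  cap <- stats::setNames(vapply(ends, cap_of, integer(1)), ends)
  ui <- match(u, ends)
  vi <- match(v, ends)
  tol <- 1e-12
  best_w <- -Inf
  best_sel <- integer(0)
  cur <- integer(0)
  rec <- function(i, curw, cap) {
    if (i > m) {
      if (curw > best_w + tol ||
          (abs(curw - best_w) <= tol && lex_smaller(cur, best_sel))) {
        best_w <<- curw
        best_sel <<- cur
      }
      return(invisible())
    }
    if (curw + suffix[i] < best_w - tol) return(invisible())
    need <- if (ui[i] == vi[i]) 2L else 1L
    if (cap[ui[i]] >= need && (ui[i] == vi[i] || cap[vi[i]] >= 1L)) {
      cap2 <- cap
      cap2[ui[i]] <- cap2[ui[i]] - need
      if (ui[i] != vi[i]) cap2[vi[i]] <- cap2[vi[i]] - 1L
      cur[length(cur) + 1] <<- i
      rec(i + 1L, curw + w[i], cap2)
      cur <<- cur[-length(cur)]
    }
    rec(i + 1L, curw, cap)
    invisible()
  }
  rec(1L, 0, cap)
  list(selected = sub$key[best_sel], weight = if (is.finite(best_w)) best_w else 0)
}

# lexicographic comparison of increasing integer rank vectors; shorter
# prefix-equal vector wins (fewer, earlier edges preferred on ties)
lex_smaller <- function(a, b) {
  if (length(b) == 0) return(length(a) > 0)
  n <- min(length(a), length(b))
  for (k in seq_len(n)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  length(a) < length(b)
}

#' Solve the adjacency selection on every segment
#'
#' @param edges localized adjacency edge data.frame.
#' @param segments list of segments (across CARs; each tagged with its CAR).
#' @param psi_inv region -> localization map.
#' @param mu_loc named integer copy numbers.
#' @return list of per-segment solutions: each with \code{segment},
#'   \code{vertices}, \code{selected}, \code{weight}.
#' @export
solve_all_segments <- function(edges, segments, psi_inv, mu_loc) {
  lapply(segments, function(seg) {
    gsub <- induced_subgraph(edges, seg, psi_inv, mu_loc)
    sol <- select_adjacencies(gsub$edges, mu_loc)
    list(segment = seg, vertices = gsub$vertices,
         selected = sol$selected, weight = sol$weight)
  })
}
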
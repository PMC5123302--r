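# Merging per-segment solutions into one gene order per CAR.
#
# Every adjacency kept by at least one segment enters a consensus graph
# with weight w = P / T, where P counts segments whose solution kept the
# edge and T counts segments whose induced vertex set contained both
# endpoints.  The graph is pruned greedily to the copy numbers, then
# traversed in rank order (leftmost CAR position first) to produce signed
# paths of localizations.

#' Merge per-segment solutions into a consensus graph
#'
#' @param solutions list of per-segment solutions from
#'   \code{\link{solve_all_segments}}.
#' @return data.frame of consensus edges: key, u, v, P, T, w.
#' @export
merge_solutions <- function(solutions) {
  kept <- unlist(lapply(solutions, `[[`, "selected"), use.names = FALSE)
  if (length(kept) == 0) {
    return(data.frame(key = character(0), u = character(0), v = character(0),
                      P = integer(0), T = integer(0), w = numeric(0)))
  }
  P <- table(kept)
  keys <- names(P)
  ends <- strsplit(keys, "--", fixed = TRUE)
  u <- vapply(ends, `[`, character(1), 1)
  v <- vapply(ends, `[`, character(1), 2)
  lu <- loc_family_of_end(u)
  lv <- loc_family_of_end(v)
  T <- integer(length(keys))
  for (sol in solutions) {
    T <- T + as.integer(lu %in% sol$vertices & lv %in% sol$vertices)
  }
  out <- data.frame(key = keys, u = u, v = v,
                    P = as.integer(P), T = T,
                    w = as.integer(P) / T)
  stopifnot(all(out$T >= out$P), all(out$w > 0), all(out$w <= 1))
  rownames(out) <- NULL
  out
}

# marker-end degrees of a consensus edge set (self-loops count twice)
end_degrees <- function(cg) {
  table(c(cg$u, cg$v))
}

#' Prune the consensus graph to the copy numbers
#'
#' While some marker end has more incident adjacencies than its
#' localization's copy number, the lowest-weight adjacency incident to an
#' over-degree end is deleted (ties broken by removing the
#' lexicographically larger edge key).
#'
#' @param cg consensus edge data.frame from \code{\link{merge_solutions}}.
#' @param mu_loc named integer copy numbers per localization.
#' @return pruned consensus edge data.frame (degree-feasible).
#' @export
prune_to_copy_numbers <- function(cg, mu_loc) {
  cap_of <- function(end) {
    m <- mu_loc[loc_family_of_end(end)]
    ifelse(is.na(m), 0L, as.integer(m))
  }
  repeat {
    if (nrow(cg) == 0) break
    deg <- end_degrees(cg)
    caps <- vapply(names(deg), cap_of, integer(1))
    over <- names(deg)[as.integer(deg) > caps]
    if (length(over) == 0) break
    cand <- which(cg$u %in% over | cg$v %in% over)
    sub <- cg[cand, ]
    pick <- cand[order(sub$w, -rank(sub$key))][1]
    cg <- cg[-pick, , drop = FALSE]
  }
  rownames(cg) <- NULL
  cg
}

#' Rank localizations by CAR position
#'
#' Total preorder: localizations whose leftmost associated region lies
#' earlier on its CAR rank higher; remaining ties broken by the rightmost
#' associated region.  Localizations on different CARs are ordered by CAR.
#' Localizations sharing the same region span share the same rank (the
#' traversal's tie rules apply between them).
#'
#' @param psi named list: localization -> associated region keys.
#' @param cars list of CAR extremity sequences (defines the CAR order).
#' @param region_pos region position lookup from \code{car_region_index}.
#' @return named numeric vector of ranks (1 = highest; equal values mark
#'   rank ties).
#' @export
rank_localizations <- function(psi, cars, region_pos) {
  locs <- names(psi)
  car_order <- stats::setNames(seq_along(cars), names(cars))
  key <- t(vapply(locs, function(lk) {
    rs <- psi[[lk]]
    if (length(rs) == 0) return(c(Inf, Inf))
    pos <- vapply(rs, function(r) {
      rp <- region_pos[[r]]
      if (is.null(rp)) return(NA_real_)
      car_order[[rp$car]] * 1e6 + rp$pos
    }, numeric(1))
    pos <- pos[!is.na(pos)]
    if (length(pos) == 0) return(c(Inf, Inf))
    c(min(pos), max(pos))
  }, numeric(2)))
  # dense rank over the (leftmost, rightmost) span: ties share a rank
  ord <- order(key[, 1], key[, 2])
  rank <- numeric(length(locs))
  r <- 0
  last <- c(-Inf, -Inf)
  for (i in ord) {
    if (key[i, 1] != last[1] || key[i, 2] != last[2]) {
      r <- r + 1
      last <- unname(key[i, ])
    }
    rank[i] <- r
  }
  stats::setNames(rank, locs)
}

#' Traverse the pruned consensus graph into ordered paths
#'
#' Starting from the highest-ranked localization with remaining copies,
#' follows unique neighbours; at branch points follows the highest-ranked
#' neighbour with unused copies.  On a rank tie a neighbour of the same
#' gene family (a tandem continuation) is preferred — deferring it would
#' strand an adjacency only realisable at this family's own ends; other
#' rank ties spawn separate branch paths, appended in order of the rank of
#' their ending vertex.  Each top-level path is also extended backwards
#' from its starting localization's free end, so a traversal started in
#' the interior of a chain still emits the whole chain.  A copy is
#' consumed on every arrival, so emitted paths are necessarily acyclic (an
#' edge that would close a cycle is never traversed).  Localizations left
#' entirely unused become singleton paths.
#'
#' @param cg pruned consensus edge data.frame.
#' @param ranking named rank vector from \code{\link{rank_localizations}}
#'   (equal values are rank ties).
#' @param mu_loc named integer copy numbers.
#' @return list of paths; each a data.frame with columns loc, sign.
#' @export
traverse <- function(cg, ranking, mu_loc) {
  rem <- mu_loc
  nE <- nrow(cg)
  used <- rep(FALSE, nE)
  # incidence index: marker-end key -> edge row indices
  inc <- split(c(seq_len(nE), seq_len(nE)), c(cg$u, cg$v))
  emitted <- stats::setNames(rep(FALSE, length(mu_loc)), names(mu_loc))
  paths <- list()
  rank_of <- function(loc) {
    r <- ranking[loc]
    ifelse(is.na(r), Inf, r)
  }
  candidates <- function(endkey) {
    idx <- unique(inc[[endkey]])
    if (is.null(idx)) return(integer(0))
    idx <- idx[!used[idx]]
    if (length(idx) == 0) return(integer(0))
    tgt <- ifelse(cg$u[idx] == endkey, cg$v[idx], cg$u[idx])
    r <- rem[loc_family_of_end(tgt)]
    idx[which(!is.na(r) & r > 0)]
  }
  # pick the next edge out of endkey for a walk at localization `loc`:
  # highest-ranked target; ties prefer a same-family (tandem) target;
  # returns list(edge =, branch = tied edge set) with branch non-NULL when
  # a genuine multi-family tie must spawn branches
  next_step <- function(ek, loc) {
    cs <- candidates(ek)
    if (length(cs) == 0) return(NULL)
    tgt <- ifelse(cg$u[cs] == ek, cg$v[cs], cg$u[cs])
    # a same-family (tandem) continuation is taken before any rank
    # comparison: such an adjacency is only realisable at this family's
    # own ends, so deferring it strands it once the copies are used up
    tfam <- loc_family(loc_family_of_end(tgt))
    tandem <- cs[tfam == loc_family(loc)]
    if (length(tandem)) {
      tandem <- tandem[order(cg$key[tandem])]
      return(list(edge = tandem[1]))
    }
    tr <- rank_of(loc_family_of_end(tgt))
    tied <- cs[tr == min(tr)]
    tied <- tied[order(cg$key[tied])]
    if (length(tied) == 1) return(list(edge = tied))
    list(branch = tied)
  }
  take_edge <- function(i, ek) {
    t_end <- if (cg$u[i] == ek) cg$v[i] else cg$u[i]
    used[i] <<- TRUE
    nloc <- loc_family_of_end(t_end)
    rem[nloc] <<- rem[nloc] - 1L
    emitted[nloc] <<- TRUE
    list(loc = nloc, entry = marker_side(t_end))
  }
  # build one path starting at loc (copy already consumed), exiting via
  # exit_end; appends to paths via <<-
  build <- function(loc, sign) {
    path_loc <- loc
    path_sign <- sign
    exit_end <- if (sign == 1) "h" else "t"
    repeat {
      ek <- marker_key(loc, exit_end)
      st <- next_step(ek, loc)
      if (is.null(st)) break
      if (!is.null(st$edge)) {
        nxt <- take_edge(st$edge, ek)
        nsign <- if (nxt$entry == "t") 1L else -1L
        path_loc <- c(path_loc, nxt$loc)
        path_sign <- c(path_sign, nsign)
        loc <- nxt$loc
        exit_end <- other_side(nxt$entry)
      } else {
        # rank tie between families: close the current path, build each
        # tied branch as its own path, append in order of the rank of
        # their ending vertex
        paths[[length(paths) + 1]] <<- data.frame(loc = path_loc, sign = path_sign)
        branch_paths <- list()
        for (i in st$branch) {
          if (used[i]) next
          t_end <- if (cg$u[i] == ek) cg$v[i] else cg$u[i]
          if (rem[loc_family_of_end(t_end)] <= 0) next
          nxt <- take_edge(i, ek)
          nsign <- if (nxt$entry == "t") 1L else -1L
          before <- length(paths)
          build(nxt$loc, nsign)
          branch_paths[[length(branch_paths) + 1]] <-
            paths[(before + 1):length(paths)]
          paths <<- paths[seq_len(before)]
        }
        endr <- vapply(branch_paths, function(pl) {
          p <- pl[[1]]
          rank_of(p$loc[nrow(p)])
        }, numeric(1))
        for (b in order(endr)) {
          paths <<- c(paths, branch_paths[[b]])
        }
        return(invisible())
      }
    }
    paths[[length(paths) + 1]] <<- data.frame(loc = path_loc, sign = path_sign)
    invisible()
  }
  # extend a finished top-level path leftwards from its start's free end;
  # stops at multi-family rank ties (left for later traversals)
  extend_back <- function(p) {
    loc <- p$loc[1]
    free <- if (p$sign[1] == 1) "t" else "h"
    repeat {
      ek <- marker_key(loc, free)
      st <- next_step(ek, loc)
      if (is.null(st) || is.null(st$edge)) break
      nxt <- take_edge(st$edge, ek)
      # the neighbour precedes the path: its trailing end faces the edge
      nsign <- if (nxt$entry == "h") 1L else -1L
      p <- rbind(data.frame(loc = nxt$loc, sign = nsign), p)
      loc <- nxt$loc
      free <- other_side(nxt$entry)
    }
    rownames(p) <- NULL
    p
  }
  rank_sorted <- names(ranking)[order(ranking, names(ranking))]
  repeat {
    start <- NULL
    for (lk in rank_sorted) {
      if (!is.na(rem[lk]) && rem[lk] > 0 &&
          (length(candidates(marker_key(lk, "h"))) > 0 ||
           length(candidates(marker_key(lk, "t"))) > 0)) {
        start <- lk
        break
      }
    }
    if (is.null(start)) break
    rem[start] <- rem[start] - 1L
    emitted[start] <- TRUE
    # exit towards the better-ranked side; ties exit via the head
    rank_side <- function(end) {
      ek <- marker_key(start, end)
      cs <- candidates(ek)
      if (length(cs) == 0) return(Inf)
      tgt <- ifelse(cg$u[cs] == ek, cg$v[cs], cg$u[cs])
      min(rank_of(loc_family_of_end(tgt)))
    }
    sgn <- if (rank_side("h") <= rank_side("t")) 1L else -1L
    first_idx <- length(paths) + 1L
    build(start, sgn)
    paths[[first_idx]] <- extend_back(paths[[first_idx]])
  }
  # singleton paths for localizations never used anywhere
  for (lk in rank_sorted) {
    if (!emitted[lk] && !is.na(rem[lk]) && rem[lk] > 0) {
      paths[[length(paths) + 1]] <- data.frame(loc = lk, sign = 1L)
    }
  }
  paths
}

#' Collapse localization paths to signed gene sequences per CAR
#'
#' Paths are grouped by the CAR of their starting localization and kept in
#' traversal order (which follows the rank of their endpoints); each
#' localization is collapsed back to its gene family.
#'
#' @param paths list of localization paths from \code{\link{traverse}}.
#' @param loc_car named character vector: localization -> CAR id.
#' @param cars list of CARs (defines CAR order).
#' @return named list (per CAR) of lists of data.frames (family, sign).
#' @export
orient_and_emit <- function(paths, loc_car, cars) {
  out <- stats::setNames(vector("list", length(cars)), names(cars))
  for (p in paths) {
    car <- unname(loc_car[p$loc[1]])
    if (is.na(car) || !car %in% names(out)) car <- names(cars)[1]
    gp <- data.frame(family = loc_family(p$loc), sign = p$sign,
                     loc = p$loc)
    out[[car]] <- c(out[[car]], list(gp))
  }
  out
}
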
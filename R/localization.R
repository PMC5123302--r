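# Partitioning gene families into localizations.
#
# A window of length l on a CAR is a run of l consecutive extremities,
# spanning l-1 regions.  A family is split into one localization per
# selected window: a window qualifies for family g if it spans regions r,
# r' containing g in two species whose tree path crosses the marked
# ancestor, with r, r' spanned by no other selected window.  Window-subset
# selection is a deterministic greedy left-to-right scan (the defining
# property admits many subsets; the scan is order-stable and favours
# leftmost windows).  Families with no qualifying window keep a single
# default localization carrying all their CAR regions.

# Regions of a CAR in positional order; odd positions are block regions.
car_region_sequence <- function(ext) {
  n <- length(ext)
  if (n < 2) return(character(0))
  region_key(ext[-n], ext[-1])
}

# region key -> (car, index) lookup over all CARs
car_region_index <- function(cars) {
  idx <- list()
  for (car in names(cars)) {
    rs <- car_region_sequence(cars[[car]])
    for (j in seq_along(rs)) idx[[rs[j]]] <- list(car = car, pos = j)
  }
  idx
}

#' Enumerate windows on a CAR
#'
#' All sliding windows of \code{l} consecutive extremities (stride 1).
#'
#' @param ext extremity sequence of one CAR.
#' @param l window length in extremities (\code{>= 3}).
#' @return list of windows; each a list with \code{start} (extremity index)
#'   and \code{regions} (the \code{l - 1} spanned region keys).
#' @export
enumerate_windows <- function(ext, l) {
  if (l < 3) stop("window length must be >= 3")
  n <- length(ext)
  if (l > n) stop("window length exceeds CAR length")
  rs <- car_region_sequence(ext)
  lapply(seq_len(n - l + 1), function(i) {
    list(start = i, regions = rs[i:(i + l - 2)])
  })
}

# All windows over all CARs, ordered by (CAR, start).  CARs shorter than l
# contribute a single whole-CAR window.
all_windows <- function(cars, l) {
  out <- list()
  for (car in names(cars)) {
    ext <- cars[[car]]
    ws <- if (length(ext) < l) {
      list(list(start = 1L, regions = car_region_sequence(ext)))
    } else {
      enumerate_windows(ext, l)
    }
    for (w in ws) {
      w$car <- car
      out[[length(out) + 1]] <- w
    }
  }
  out
}

#' Compute the localizations of one gene family
#'
#' Greedy left-to-right selection of a window subset satisfying the
#' localization property; one localization per selected window.
#'
#' @param family family id.
#' @param windows list of windows from \code{\link{all_windows}}.
#' @param region_species named list: CAR region key -> character vector of
#'   species in which the family is contained in that region.
#' @param tree a \code{multires_tree}.
#' @param region_pos named list from \code{car_region_index}.
#' @return list of localizations; each a list with \code{loc} (key),
#'   \code{family}, \code{car}, \code{win_start}, \code{psi} (region keys),
#'   \code{default} (logical).
#' @export
compute_localizations <- function(family, windows, region_species, tree,
                                  region_pos) {
  fam_regions <- names(region_species)[lengths(region_species) > 0]
  if (length(fam_regions) == 0) return(list())
  smat <- straddle_matrix(tree, unique(unlist(region_species)))
  straddles <- function(r1, r2) {
    s1 <- region_species[[r1]]; s2 <- region_species[[r2]]
    any(smat[s1, s2, drop = FALSE])
  }
  claimed <- character(0)
  spans_selected <- character(0)
  selected <- list()
  for (w in windows) {
    rw <- w$regions
    if (any(rw %in% claimed)) next
    cand <- setdiff(intersect(rw, fam_regions), spans_selected)
    if (length(cand) == 0) next
    # order candidates by position within the window for determinism
    cand <- cand[order(match(cand, rw))]
    support <- NULL
    for (i in seq_along(cand)) {
      for (j in i:length(cand)) {
        if (straddles(cand[i], cand[j])) {
          support <- c(cand[i], cand[j])
          break
        }
      }
      if (!is.null(support)) break
    }
    if (is.null(support)) next
    selected[[length(selected) + 1]] <- list(window = w, support = unique(support))
    claimed <- union(claimed, support)
    spans_selected <- union(spans_selected, rw)
  }
  if (length(selected) == 0) {
    return(list(list(loc = loc_key(family, 1L), family = family,
                     car = region_pos[[fam_regions[1]]]$car,
                     win_start = NA_integer_, psi = fam_regions,
                     default = TRUE)))
  }
  # assign each family region to one localization (psi disjointness):
  # the earliest-selected window spanning it, else the nearest window on
  # the same CAR, else the first localization.
  psi <- vector("list", length(selected))
  for (r in fam_regions) {
    owner <- NA_integer_
    for (k in seq_along(selected)) {
      if (r %in% selected[[k]]$window$regions) { owner <- k; break }
    }
    if (is.na(owner)) {
      rp <- region_pos[[r]]
      best <- Inf
      for (k in seq_along(selected)) {
        w <- selected[[k]]$window
        if (!is.null(rp) && w$car == rp$car) {
          dist <- min(abs(rp$pos - (w$start:(w$start + length(w$regions) - 1))))
          if (dist < best) { best <- dist; owner <- k }
        }
      }
      if (is.na(owner)) owner <- 1L
    }
    psi[[owner]] <- c(psi[[owner]], r)
  }
  lapply(seq_along(selected), function(k) {
    w <- selected[[k]]$window
    list(loc = loc_key(family, k), family = family, car = w$car,
         win_start = w$start, psi = psi[[k]] %||% character(0),
         default = FALSE)
  })
}

#' Rebalance localization copy numbers to the family copy number
#'
#' Two-step heuristic: (i) localizations involved in no adjacency are
#' deleted; (ii) while the localization copy numbers sum to more than the
#' family copy number, the localization with the highest copy number is
#' decremented (ties: the one whose leftmost associated region lies
#' rightmost on its CAR).  If the sum falls short of the family copy
#' number, the localization with the lowest copy number is incremented
#' (ties: leftmost region).
#'
#' @param mu_loc named integer vector of initial localization copy numbers.
#' @param mu_family the family's ancestral copy number.
#' @param degree named integer vector: number of adjacencies incident to
#'   each localization in the localized adjacency graph.
#' @param psi_pos named numeric vector: CAR position of each localization's
#'   leftmost associated region (used only for tie-breaking).
#' @return named integer vector of rebalanced copy numbers; localizations
#'   deleted by rule (i) are absent.  Returns an empty vector (with a
#'   warning upstream) when every localization is deleted.
#' @export
rebalance_copy_numbers <- function(mu_loc, mu_family, degree, psi_pos) {
  keep <- names(mu_loc)[degree[names(mu_loc)] > 0 & !is.na(degree[names(mu_loc)])]
  mu <- mu_loc[keep]
  if (length(mu) == 0) return(mu)
  pos <- psi_pos[names(mu)]
  while (sum(mu) > mu_family) {
    mx <- which(mu == max(mu))
    pick <- mx[order(-pos[mx], names(mu)[mx])][1]
    mu[pick] <- mu[pick] - 1L
  }
  while (sum(mu) < mu_family) {
    mn <- which(mu == min(mu))
    pick <- mn[order(pos[mn], names(mu)[mn])][1]
    mu[pick] <- mu[pick] + 1L
  }
  mu
}

# Build the complete localization set for all families.
#
# containment: containment_table restricted rows; cars: list of extremity
# sequences; mu: family copy numbers; window: window length l.
# Returns list(locs, psi, region2loc, windows).
build_localizations <- function(genes, tree, cars, containment, mu, window) {
  region_pos <- car_region_index(cars)
  car_regions <- names(region_pos)
  ct <- containment[containment$region %in% car_regions, , drop = FALSE]
  windows <- all_windows(cars, window)
  fams <- names(mu)[mu > 0]
  fams <- intersect(fams, unique(ct$family))
  # per family: region -> species set
  locs <- list()
  psi <- list()
  region2loc <- new.env(parent = emptyenv())
  # pre-index windows by region for speed
  win_regions <- lapply(windows, `[[`, "regions")
  region2win <- split(rep(seq_along(windows), lengths(win_regions)),
                      unlist(win_regions, use.names = FALSE))
  for (fam in fams) {
    sub <- ct[ct$family == fam, ]
    rs <- split(sub$species, sub$region)
    rs <- lapply(rs, unique)
    widx <- sort(unique(unlist(region2win[names(rs)], use.names = FALSE)))
    ll <- compute_localizations(fam, windows[widx], rs, tree, region_pos)
    for (l in ll) {
      locs[[l$loc]] <- l
      psi[[l$loc]] <- l$psi
      for (r in l$psi) assign(paste(fam, r, sep = "\r"), l$loc, envir = region2loc)
    }
  }
  list(locs = locs, psi = psi, region2loc = region2loc, windows = windows,
       region_pos = region_pos)
}

# Initial copy number of each localization: integer small parsimony on the
# per-leaf counts of occurrences contained in the localization's regions.
initial_loc_mu <- function(lset, containment, mu, tree) {
  car_ct <- containment[containment$region %in% names(lset$region_pos), ]
  out <- integer(0)
  for (lk in names(lset$locs)) {
    l <- lset$locs[[lk]]
    sub <- car_ct[car_ct$family == l$family & car_ct$region %in% l$psi, ]
    if (nrow(sub) == 0) { out[lk] <- 0L; next }
    counts <- vapply(split(sub$occ, sub$species),
                     function(x) length(unique(x)), integer(1))
    m <- ancestral_copy_number(counts, tree)
    out[lk] <- min(m, mu[[l$family]])
  }
  out
}

#' Build the localized adjacency graph
#'
#' Every conserved marker adjacency is re-attached to localizations: each
#' extant adjacency instance maps its two gene occurrences to localizations
#' through the regions containing them, the instance's species evidence is
#' re-collected per localized edge, and an edge is kept when some
#' straddling species pair supports it.  Edge weights are recomputed from
#' the localized evidence.
#'
#' @param marker_graph the marker-level \code{adjacency_graph} (only
#'   adjacencies conserved at marker level are eligible).
#' @param lset localization set from \code{build_localizations}.
#' @param genes gene-order data.frame.
#' @param containment containment table.
#' @param tree a \code{multires_tree}.
#' @param scheme weight scheme.
#' @return data.frame of localized edges: key, u, v (localization marker
#'   ends), weight.
#' @export
localize_adjacencies <- function(marker_graph, lset, genes, containment,
                                 tree, scheme = "pair-count") {
  conserved_keys <- marker_graph$edges$key[marker_graph$edges$type == "adjacency"]
  car_ct <- containment[containment$region %in% names(lset$region_pos), ]
  car_ct <- car_ct[order(car_ct$occ, car_ct$l_a), ]
  # occurrence -> localization via its leftmost containing CAR region
  first <- !duplicated(car_ct$occ)
  occ_loc <- character(0)
  keymap <- paste(car_ct$family[first], car_ct$region[first], sep = "\r")
  locs <- vapply(keymap, function(k) {
    if (exists(k, envir = lset$region2loc)) get(k, envir = lset$region2loc)
    else NA_character_
  }, character(1))
  occ_loc[as.character(car_ct$occ[first])] <- locs
  # walk every chromosome, collect localized adjacency instances
  inst_edge <- character(0)
  inst_species <- character(0)
  inst_mkey <- character(0)
  for (chr in split(genes, paste(genes$species, genes$chrom, sep = "\r"))) {
    chr <- chr[order(chr$start), ]
    n <- nrow(chr)
    if (n < 2) next
    l1 <- occ_loc[as.character(chr$occ[-n])]
    l2 <- occ_loc[as.character(chr$occ[-1])]
    # marker ends facing the adjacency: right end of gene i, left end of i+1
    e1 <- ifelse(chr$sign[-n] == 1, "h", "t")
    e2 <- ifelse(chr$sign[-1] == 1, "t", "h")
    ok <- !is.na(l1) & !is.na(l2)
    if (!any(ok)) next
    m1 <- marker_key(chr$family[-n], e1)[ok]
    m2 <- marker_key(chr$family[-1], e2)[ok]
    u <- marker_key(l1[ok], e1[ok])
    v <- marker_key(l2[ok], e2[ok])
    inst_edge <- c(inst_edge, pair_key(u, v))
    inst_mkey <- c(inst_mkey, pair_key(m1, m2))
    inst_species <- c(inst_species, rep(chr$species[1], sum(ok)))
  }
  keep <- inst_mkey %in% conserved_keys
  inst_edge <- inst_edge[keep]
  inst_species <- inst_species[keep]
  if (length(inst_edge) == 0) {
    return(data.frame(key = character(0), u = character(0), v = character(0),
                      weight = numeric(0)))
  }
  sp_of <- lapply(split(inst_species, inst_edge), unique)
  species <- unique(inst_species)
  smat <- straddle_matrix(tree, species)
  rows <- list()
  for (key in names(sp_of)) {
    sps <- sp_of[[key]]
    if (length(sps) < 2) next
    sub <- smat[sps, sps, drop = FALSE]
    idx <- which(upper.tri(sub) & sub, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    ev <- cbind(sps[idx[, 1]], sps[idx[, 2]])
    ends <- strsplit(key, "--", fixed = TRUE)[[1]]
    rows[[key]] <- data.frame(key = key, u = ends[1], v = ends[2],
                              weight = adjacency_weight(ev, tree, scheme))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(key = character(0), u = character(0), v = character(0),
                      weight = numeric(0))
  }
  rownames(out) <- NULL
  out
}

# Apply copy-number rebalancing across all families; returns the final
# named mu vector over surviving localizations (families whose
# localizations are all deleted are dropped with a warning).
rebalance_all <- function(lset, mu_loc0, mu, edges) {
  deg_tab <- table(c(loc_family_of_end(edges$u), loc_family_of_end(edges$v)))
  degree <- stats::setNames(as.integer(deg_tab), names(deg_tab))
  psi_pos <- vapply(names(lset$locs), function(lk) {
    rs <- lset$psi[[lk]]
    if (length(rs) == 0) return(Inf)
    min(vapply(rs, function(r) lset$region_pos[[r]]$pos, numeric(1)))
  }, numeric(1))
  fams <- unique(vapply(lset$locs, `[[`, character(1), "family"))
  out <- integer(0)
  for (fam in fams) {
    lk <- names(lset$locs)[vapply(lset$locs, function(l) l$family == fam, logical(1))]
    deg <- stats::setNames(ifelse(lk %in% names(degree), degree[lk], 0L), lk)
    mu_f <- rebalance_copy_numbers(mu_loc0[lk], mu[[fam]], deg, psi_pos)
    if (length(mu_f) == 0) {
      warning("family ", fam, " dropped: no localization carries an adjacency")
      next
    }
    out <- c(out, mu_f)
  }
  out
}

# localization key of a localization marker end ("fam@k:h" -> "fam@k")
loc_family_of_end <- function(end) sub(":[ht]$", "", end)
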
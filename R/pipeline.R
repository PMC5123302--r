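# Pipeline orchestration: containments -> conserved adjacencies + copy
# numbers -> localizations -> segments -> optimization -> consensus.

#' Reconstruct an ancestral gene order
#'
#' Runs the full reconstruction at the marked ancestor of the species
#' tree, guided by the CARs of a synteny-level reconstruction.
#'
#' @param tree a \code{multires_tree}.
#' @param genes extant gene orders (data.frame from
#'   \code{\link{read_gene_orders}} or a \code{multires_sim}'s
#'   \code{$genes}).
#' @param blocks extant synteny block occurrences.
#' @param cars list of CAR extremity sequences.
#' @param window window length in extremities (default 25).
#' @param segment segment length in extremities (default 65; must be
#'   \code{>= window}).
#' @param stride segment stride (default \code{floor(segment / 2)}).
#' @param weight_scheme adjacency weight scheme
#'   (\code{\link{adjacency_weight}}).
#' @param max_copies families with inferred ancestral copy number above
#'   this cap are discarded (default 15).
#' @param verbose log per-stage counters via \code{message()}.
#' @return object of class \code{multires}: list with \code{paths} (per
#'   CAR, list of signed family data.frames), \code{psi} (localization ->
#'   regions), \code{mu} (family copy numbers), \code{mu_loc}
#'   (localization copy numbers), \code{consensus} (pruned consensus edge
#'   table), \code{counts} (stage telemetry), \code{params}.
#' @export
multires <- function(tree, genes, blocks, cars,
                     window = 25, segment = 65,
                     stride = max(1L, segment %/% 2L),
                     weight_scheme = c("pair-count", "branch-decay"),
                     max_copies = 15, verbose = FALSE) {
  weight_scheme <- match.arg(weight_scheme)
  if (inherits(genes, "multires_sim")) {
    sim <- genes
    genes <- sim$genes; blocks <- sim$blocks; cars <- sim$cars
  }
  if (segment < window) stop("segment length must be at least the window length")
  if (window < 3) stop("window length must be >= 3")
  car_blocks <- unique(marker_id(unlist(cars, use.names = FALSE)))
  unknown <- setdiff(car_blocks, unique(blocks$block))
  if (length(unknown)) {
    stop("CAR references unknown block(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  say <- function(...) if (verbose) message("[multires] ", sprintf(...))
  counts <- list()

  # stage 1: extant containments
  regions <- extant_regions(blocks)
  ct <- containment_table(genes, regions)
  counts$region_occurrences <- nrow(regions)
  counts$containments <- nrow(ct)
  say("containment: %d region occurrences, %d gene-region containments",
      nrow(regions), nrow(ct))

  # stage 2: ancestral copy numbers and conserved adjacencies
  mu <- ancestral_copy_numbers(genes, tree)
  genes_f <- filter_families(genes, mu, max_copies)
  mu <- mu[mu > 0 & mu <= max_copies]
  counts$families <- length(mu)
  cons <- conserved_adjacencies(genes_f, tree)
  mgraph <- build_marker_adjacency_graph(cons, mu, tree, weight_scheme)
  counts$conserved_marker_adjacencies <- length(cons$edges)
  say("conservation: %d families kept (cap %s), %d conserved marker adjacencies",
      length(mu), as.character(max_copies), length(cons$edges))

  # stage 3: localizations
  ct_f <- ct[ct$family %in% names(mu), , drop = FALSE]
  lset <- build_localizations(genes_f, tree, cars, ct_f, mu, window)
  mu_loc0 <- initial_loc_mu(lset, ct_f, mu, tree)
  ledges <- localize_adjacencies(mgraph, lset, genes_f, ct_f, tree, weight_scheme)
  mu_loc <- rebalance_all(lset, mu_loc0, mu, ledges)
  psi <- lset$psi[names(mu_loc)]
  counts$localizations <- length(mu_loc)
  counts$localized_adjacencies <- nrow(ledges)
  say("localization: %d localizations over %d families, %d localized adjacencies",
      length(mu_loc), length(unique(loc_family(names(mu_loc)))), nrow(ledges))

  # stage 4: segments and per-segment optimization
  segments <- list()
  for (car in names(cars)) {
    for (s in enumerate_segments(cars[[car]], segment, stride)) {
      s$car <- car
      segments[[length(segments) + 1]] <- s
    }
  }
  psi_inv <- psi_inverse(psi)
  sols <- solve_all_segments(ledges, segments, psi_inv, mu_loc)
  counts$segments <- length(segments)
  counts$selected_total <- sum(vapply(sols, function(s) length(s$selected), integer(1)))
  say("optimizer: %d segments, %d adjacency selections in total",
      length(segments), counts$selected_total)

  # stage 5: consensus
  cg <- merge_solutions(sols)
  cg <- prune_to_copy_numbers(cg, mu_loc)
  ranking <- rank_localizations(psi, cars, lset$region_pos)
  paths <- traverse(cg, ranking, mu_loc)
  loc_car <- vapply(lset$locs, function(l) l$car %||% NA_character_, character(1))
  emitted <- orient_and_emit(paths, loc_car, cars)
  counts$consensus_edges <- nrow(cg)
  counts$fragments <- length(paths)
  say("consensus: %d edges kept after pruning, %d fragments emitted",
      nrow(cg), length(paths))

  structure(list(paths = emitted, psi = psi, mu = mu, mu_loc = mu_loc,
                 consensus = cg, counts = counts,
                 params = list(window = window, segment = segment,
                               stride = stride,
                               weight_scheme = weight_scheme,
                               max_copies = max_copies)),
            class = "multires")
}

#' @export
print.multires <- function(x, ...) {
  nfrag <- sum(vapply(x$paths, length, integer(1)))
  ngene <- sum(vapply(unlist(x$paths, recursive = FALSE),
                      nrow, integer(1)))
  cat(sprintf("Ancestral gene-order reconstruction (window %d, segment %d)\n",
              x$params$window, x$params$segment))
  cat(sprintf("  %d fragments over %d CARs; %d gene copies placed; %d families\n",
              nfrag, length(x$paths), ngene, length(x$mu)))
  invisible(x)
}

#' @export
summary.multires <- function(object, ...) {
  cat(sprintf("Ancestral gene-order reconstruction (window %d, segment %d, stride %d, %s weights)\n",
              object$params$window, object$params$segment,
              object$params$stride, object$params$weight_scheme))
  cts <- object$counts
  cat("Stage counters:\n")
  for (nm in names(cts)) cat(sprintf("  %-28s %d\n", nm, cts[[nm]]))
  lens <- vapply(unlist(object$paths, recursive = FALSE), nrow, integer(1))
  if (length(lens)) {
    cat(sprintf("Fragment lengths: median %.0f, max %d genes\n",
                stats::median(lens), max(lens)))
  }
  invisible(object)
}

#' Parameter sweep over window and segment lengths
#'
#' Reconstructs a simulated data set for every (window, segment) pair with
#' \code{segment >= window} (or strict inequality) and evaluates each
#' reconstruction against the simulated truth.
#'
#' @param sim a \code{multires_sim}.
#' @param windows integer vector of window lengths.
#' @param segments integer vector of segment lengths.
#' @param strict require \code{segment > window} instead of \code{>=}.
#' @param ... further arguments passed to \code{\link{multires}}.
#' @return data.frame with one row per pair: window, segment, tp_rate,
#'   fp_rate, fragments, genes_recovered.
#' @export
multires_sweep <- function(sim, windows, segments, strict = FALSE, ...) {
  stopifnot(inherits(sim, "multires_sim"))
  if (length(windows) == 0 || length(segments) == 0) {
    stop("empty window or segment value list")
  }
  grid <- expand.grid(window = windows, segment = segments)
  keep <- if (strict) grid$segment > grid$window else grid$segment >= grid$window
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0) stop("no valid (window, segment) pairs")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rec <- multires(sim$tree, sim, window = grid$window[i],
                    segment = grid$segment[i], ...)
    ev <- evaluate_reconstruction(rec, sim)
    data.frame(window = grid$window[i], segment = grid$segment[i],
               tp_rate = ev$adjacency$tp_rate, fp_rate = ev$adjacency$fp_rate,
               fragments = ev$fragments,
               genes_recovered = ev$gene_content$recovered)
  })
  do.call(rbind, rows)
}

#' Run a reconstruction from a configuration
#'
#' Reads the inputs named in a configuration (see
#' \code{\link{read_config}}), reconstructs, and optionally writes the
#' resulting gene order.
#'
#' @param config named list (or path to a YAML file).
#' @return the \code{multires} object, invisibly if an output was written.
#' @export
multires_run <- function(config) {
  if (is.character(config)) config <- read_config(config)
  for (f in c("tree", "ancestor", "genes", "blocks", "cars")) {
    if (is.null(config[[f]])) stop("configuration misses required field: ", f)
  }
  tree <- read_tree(config$tree, config$ancestor)
  genes <- read_gene_orders(config$genes)
  blocks <- read_blocks(config$blocks)
  cars <- read_cars(config$cars)
  res <- multires(tree, genes, blocks, cars,
                  window = config$window %||% 25,
                  segment = config$segment %||% 65,
                  stride = config$stride %||% max(1L, (config$segment %||% 65) %/% 2L),
                  weight_scheme = config$weight_scheme %||% "pair-count",
                  max_copies = config$max_copies %||% 15)
  if (!is.null(config$out)) {
    write_gene_order(res, config$out)
    return(invisible(res))
  }
  res
}
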
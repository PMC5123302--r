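# Scoring a reconstruction against the true ancestral genome.
#
# Adjacencies are compared as multisets of unordered marker pairs at the
# family level (localizations re-merged to families first), so repeated
# adjacencies are neither over- nor under-credited: TP is the sum of
# per-key minimum multiplicities, FP the excess in the reconstruction, FN
# the excess in the truth.

# fragments: list of data.frames (family, sign); truth: genome as list of
# chromosomes (family, sign)
fragment_adjacencies <- function(fragments) {
  unlist(lapply(fragments, function(p) {
    chromosome_adjacencies(double_gene_order(p$family, p$sign))
  }), use.names = FALSE)
}

#' Adjacency true/false positive scores
#'
#' @param recon list of reconstructed fragments (data.frames with columns
#'   family, sign), or a \code{multires} object.
#' @param truth true ancestral genome: list of data.frames (family, sign).
#' @return list with integer components \code{TP}, \code{FP}, \code{FN}
#'   and rates \code{tp_rate} (TP / truth count) and \code{fp_rate}
#'   (FP / reconstruction count).
#' @export
adjacency_scores <- function(recon, truth) {
  frags <- reconstruction_fragments(recon)
  ra <- table(fragment_adjacencies(frags))
  ta <- table(genome_adjacencies(truth))
  common <- intersect(names(ra), names(ta))
  tp <- sum(pmin(ra[common], ta[common]))
  fp <- sum(ra) - tp
  fn <- sum(ta) - tp
  list(TP = as.integer(tp), FP = as.integer(fp), FN = as.integer(fn),
       tp_rate = as.numeric(tp / max(1, tp + fn)),
       fp_rate = as.numeric(fp / max(1, tp + fp)))
}

#' Common-interval recovery
#'
#' A common interval of k genes (2k markers) is a multiset of k families
#' occurring consecutively in both genomes, internal order and orientation
#' free.  For each k, every k-gene window of the truth is enumerated and
#' the recovered ratio is the fraction found as a consecutive window
#' anywhere in the reconstruction; windows never span fragment boundaries.
#' The comparison is an exhaustive sliding-window multiset check.
#'
#' @param recon fragments or a \code{multires} object.
#' @param truth true ancestral genome.
#' @param k_range integer vector of interval sizes in genes (k >= 3).
#' @return data.frame with columns k (genes), length (2k markers), total,
#'   recovered, ratio.
#' @export
common_interval_recovery <- function(recon, truth, k_range = 3:10) {
  stopifnot(all(k_range >= 3))
  frags <- reconstruction_fragments(recon)
  window_keys <- function(fams, k) {
    n <- length(fams)
    if (n < k) return(character(0))
    vapply(seq_len(n - k + 1), function(i) {
      paste(sort(fams[i:(i + k - 1)]), collapse = "|")
    }, character(1))
  }
  res <- lapply(k_range, function(k) {
    truth_w <- unlist(lapply(truth, function(chr) window_keys(chr$family, k)),
                      use.names = FALSE)
    recon_w <- unique(unlist(lapply(frags, function(p) window_keys(p$family, k)),
                             use.names = FALSE))
    total <- length(truth_w)
    rec <- sum(truth_w %in% recon_w)
    data.frame(k = k, length = 2L * k, total = total, recovered = rec,
               ratio = if (total > 0) rec / total else NA_real_)
  })
  do.call(rbind, res)
}

#' Number of reconstructed fragments
#'
#' @param recon fragments or a \code{multires} object.
#' @return integer count of emitted paths.
#' @export
fragment_count <- function(recon) {
  length(reconstruction_fragments(recon))
}

#' Gene content recovered
#'
#' Multiset intersection of family copies between reconstruction and
#' truth.
#'
#' @param recon fragments or a \code{multires} object.
#' @param truth true ancestral genome.
#' @return list with \code{recovered} and \code{total} (truth gene count).
#' @export
gene_content <- function(recon, truth) {
  frags <- reconstruction_fragments(recon)
  rc <- table(unlist(lapply(frags, `[[`, "family"), use.names = FALSE))
  tc <- table(unlist(lapply(truth, `[[`, "family"), use.names = FALSE))
  common <- intersect(names(rc), names(tc))
  list(recovered = as.integer(sum(pmin(rc[common], tc[common]))),
       total = as.integer(sum(tc)))
}

#' Evaluate a reconstruction against simulated truth
#'
#' @param recon a \code{multires} object or a list of fragments.
#' @param truth a \code{multires_sim} object or a true genome (list of
#'   data.frames family/sign).
#' @param k_range interval sizes for common-interval recovery.
#' @return object of class \code{multires_eval}: list with
#'   \code{adjacency}, \code{intervals}, \code{fragments},
#'   \code{gene_content}.
#' @export
evaluate_reconstruction <- function(recon, truth, k_range = 3:10) {
  genome <- if (inherits(truth, "multires_sim")) truth$ancestor else truth
  out <- list(adjacency = adjacency_scores(recon, genome),
              intervals = common_interval_recovery(recon, genome, k_range),
              fragments = fragment_count(recon),
              gene_content = gene_content(recon, genome))
  class(out) <- "multires_eval"
  out
}

#' @export
print.multires_eval <- function(x, ...) {
  a <- x$adjacency
  g <- x$gene_content
  cat("Reconstruction evaluation\n")
  cat(sprintf("  genes recovered : %d / %d (%.1f%%)\n", g$recovered, g$total,
              100 * g$recovered / max(1, g$total)))
  cat(sprintf("  adjacencies     : TP %d  FP %d  FN %d  (TP rate %.1f%%, FP rate %.1f%%)\n",
              a$TP, a$FP, a$FN, 100 * a$tp_rate, 100 * a$fp_rate))
  cat(sprintf("  fragments       : %d\n", x$fragments))
  iv <- x$intervals
  cat("  common intervals:\n")
  for (i in seq_len(nrow(iv))) {
    cat(sprintf("    k = %d (length %d): %d / %d (%.1f%%)\n", iv$k[i],
                iv$length[i], iv$recovered[i], iv$total[i], 100 * iv$ratio[i]))
  }
  invisible(x)
}

# accept either a multires object or a bare fragment list
reconstruction_fragments <- function(recon) {
  if (inherits(recon, "multires")) {
    unlist(recon$paths, recursive = FALSE, use.names = FALSE)
  } else {
    recon
  }
}
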
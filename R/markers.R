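#' Double a signed gene order into a marker sequence
#'
#' Each gene family is split into a tail and a head marker.  A gene with
#' positive orientation emits (tail, head); a negative gene emits
#' (head, tail).  Positions 2k-1 and 2k of the result are paired (they
#' belong to the same gene copy).
#'
#' @param family character vector of family identifiers along a chromosome.
#' @param sign integer vector of +1 / -1 orientations (same length).
#' @return character vector of marker keys of length \code{2 * length(family)}.
#' @export
double_gene_order <- function(family, sign) {
  stopifnot(length(family) == length(sign))
  if (length(family) == 0) return(character(0))
  if (!all(sign %in% c(-1, 1))) stop("sign must be +1 or -1")
  check_ids(family, "family id")
  first <- ifelse(sign == 1, "t", "h")
  second <- ifelse(sign == 1, "h", "t")
  out <- character(2 * length(family))
  out[seq(1, length(out), by = 2)] <- marker_key(family, first)
  out[seq(2, length(out), by = 2)] <- marker_key(family, second)
  out
}

#' Invert marker doubling
#'
#' Recovers the signed family sequence from a doubled marker sequence.
#'
#' @param markers character vector of marker keys (even length, paired).
#' @return list with components \code{family} and \code{sign}.
#' @export
undouble_markers <- function(markers) {
  n <- length(markers)
  if (n %% 2 != 0) stop("marker sequence must have even length")
  if (n == 0) return(list(family = character(0), sign = integer(0)))
  first <- markers[seq(1, n, by = 2)]
  second <- markers[seq(2, n, by = 2)]
  if (!all(marker_id(first) == marker_id(second))) {
    stop("positions 2k-1 and 2k must carry markers of the same family")
  }
  sgn <- ifelse(marker_side(first) == "t", 1L, -1L)
  bad <- marker_side(first) == marker_side(second)
  if (any(bad)) stop("paired markers must be a head and a tail")
  list(family = marker_id(first), sign = sgn)
}

# Adjacencies of a doubled linear chromosome: the unordered marker pairs at
# positions (2k, 2k+1), i.e. between consecutive genes.  Pairing edges
# (2k-1, 2k) are excluded.  Returns a character vector of canonical edge keys.
chromosome_adjacencies <- function(markers) {
  n <- length(markers)
  if (n < 4) return(character(0))
  left <- markers[seq(2, n - 2, by = 2)]
  right <- markers[seq(3, n - 1, by = 2)]
  pair_key(left, right)
}

# Adjacency keys of a whole genome (list of chromosomes, each a data.frame
# with columns family, sign), as a multiset (character vector with repeats).
genome_adjacencies <- function(genome) {
  unlist(lapply(genome, function(chr) {
    chromosome_adjacencies(double_gene_order(chr$family, chr$sign))
  }), use.names = FALSE)
}
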
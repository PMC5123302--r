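# Mapping gene occurrences into extant regions.
#
# On an extant chromosome the tracked extremities are the doubled ends of
# the block occurrences.  A block on the + strand exposes its tail at its
# genomic start and its head at its end; the - strand swaps them.  Regions
# are pairs of consecutive tracked extremities: the two ends of one block
# (a block region) or the facing ends of two neighbouring blocks (a gap
# region).  Region identity is the unordered extremity pair, so extant
# regions can be matched against CAR regions regardless of orientation.

# Region occurrences per species/chromosome.
# blocks: data.frame (species, chrom, start, end, block, sign), sorted.
# Returns data.frame: species, chrom, region (key), kind, l_a, l_b,
# e_left, e_right (extremities in genomic order).
extant_regions <- function(blocks) {
  res <- lapply(split(blocks, paste(blocks$species, blocks$chrom, sep = "\r")),
                function(b) {
    b <- b[order(b$start), ]
    left <- marker_key(b$block, ifelse(b$sign == 1, "t", "h"))
    right <- marker_key(b$block, ifelse(b$sign == 1, "h", "t"))
    n <- nrow(b)
    blk <- data.frame(species = b$species, chrom = b$chrom,
                      region = region_key(left, right), kind = "block",
                      l_a = b$start, l_b = b$end,
                      e_left = left, e_right = right)
    if (n > 1) {
      gap <- data.frame(species = b$species[-n], chrom = b$chrom[-n],
                        region = region_key(right[-n], left[-1]),
                        kind = "gap",
                        l_a = b$end[-n], l_b = b$start[-1],
                        e_left = right[-n], e_right = left[-1])
      blk <- rbind(blk, gap)
    }
    blk
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$species, out$chrom, out$l_a), ]
}

#' Half-length containment rule
#'
#' A gene occurrence with marker loci \code{x}, \code{y} is contained in a
#' region occurrence spanning \code{[l_a, l_b]} (with \code{l_a < l_b},
#' extremities consecutive on the extant chromosome) if it lies entirely
#' within the region, or if it straddles one boundary and at least half of
#' its length \code{|y - x|} lies inside.
#'
#' The straddle conditions additionally require a positive overlap with the
#' region's interior, so a zero-length gap between two abutting blocks
#' contains nothing.
#'
#' @param x,y loci of the gene's two markers (either order).
#' @param l_a,l_b loci of the region's extremities, \code{l_a <= l_b}.
#' @return logical.
#' @export
is_contained <- function(x, y, l_a, l_b) {
  lo <- pmin(x, y)
  hi <- pmax(x, y)
  len <- hi - lo
  overlap <- pmin(hi, l_b) - pmax(lo, l_a)
  (l_a <= lo & hi <= l_b) |
    (overlap > 0 &
       ((lo < l_a & l_a < hi & (hi - l_a) >= len / 2) |
        (lo < l_b & l_b < hi & (l_b - lo) >= len / 2)))
}

# Containment table: one row per (gene occurrence, region occurrence) pair
# satisfying the half-length rule.  A gene overlapping two flanking regions
# by exactly half its length is assigned to the leftmost region only.
# genes / regions as produced by read_gene_orders / extant_regions.
# Returns data.frame: species, chrom, region, kind, l_a, l_b, family, sign,
# g_start, g_end, occ.
containment_table <- function(genes, regions) {
  pieces <- list()
  gsplit <- split(genes, paste(genes$species, genes$chrom, sep = "\r"))
  rsplit <- split(regions, paste(regions$species, regions$chrom, sep = "\r"))
  for (key in intersect(names(gsplit), names(rsplit))) {
    g <- gsplit[[key]]
    r <- rsplit[[key]]
    hits <- lapply(seq_len(nrow(r)), function(j) {
      ok <- is_contained(g$start, g$end, r$l_a[j], r$l_b[j])
      if (!any(ok)) return(NULL)
      data.frame(species = r$species[j], chrom = r$chrom[j],
                 region = r$region[j], kind = r$kind[j],
                 l_a = r$l_a[j], l_b = r$l_b[j],
                 family = g$family[ok], sign = g$sign[ok],
                 g_start = g$start[ok], g_end = g$end[ok], occ = g$occ[ok])
    })
    pieces <- c(pieces, hits)
  }
  tab <- do.call(rbind, pieces)
  if (is.null(tab)) {
    return(data.frame(species = character(0), chrom = character(0),
                      region = character(0), kind = character(0),
                      l_a = integer(0), l_b = integer(0),
                      family = character(0), sign = integer(0),
                      g_start = integer(0), g_end = integer(0),
                      occ = integer(0)))
  }
  # exact half/half tie between two flanking regions: keep leftmost only
  tab <- tab[order(tab$occ, tab$l_a), ]
  dup <- duplicated(tab$occ)
  if (any(dup)) {
    drop <- logical(nrow(tab))
    for (o in unique(tab$occ[dup])) {
      idx <- which(tab$occ == o)
      glen <- tab$g_end[idx[1]] - tab$g_start[idx[1]]
      inside <- pmin(tab$g_end[idx], tab$l_b[idx]) - pmax(tab$g_start[idx], tab$l_a[idx])
      tied <- abs(inside - glen / 2) < 1e-9
      if (all(tied)) drop[idx[-1]] <- TRUE
    }
    tab <- tab[!drop, ]
  }
  rownames(tab) <- NULL
  tab
}

#' Gene sequences within extant regions
#'
#' For every region occurrence, the ordered sequence of contained gene
#' occurrences, oriented from the region's left extremity to its right
#' extremity on the extant chromosome.
#'
#' @param regions data.frame of extant region occurrences.
#' @param genes gene-order data.frame.
#' @return named list (by \code{species | chrom | region}) of data.frames
#'   with columns family, sign, g_start, g_end.
#' @export
region_gene_sequences <- function(regions, genes) {
  tab <- containment_table(genes, regions)
  out <- split(tab[, c("family", "sign", "g_start", "g_end")],
               paste(tab$species, tab$chrom, tab$region, sep = " | "))
  lapply(out, function(d) {
    d <- d[order(d$g_start), ]
    rownames(d) <- NULL
    d
  })
}
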
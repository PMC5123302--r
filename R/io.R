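# On-disk formats.
#
# Gene orders: tab-separated with a header-free 6-column layout
#   species  chromosome  start  end  strand  family
# using 1-based inclusive coordinates on disk (GFF-style); converted to
# 0-based half-open internally.
#
# Blocks: BED-like, 0-based half-open, with a leading species column:
#   species  chromosome  start  end  block  score  strand
# (score is carried but ignored).
#
# CARs: one CAR per line, whitespace-separated signed block ids
# ("+b12 -b3 b7"; a bare id means "+").  Blank lines and lines starting
# with '#' are skipped.

#' Read extant gene orders
#'
#' @param path TSV file: species, chromosome, start, end, strand, family
#'   (no header, 1-based inclusive coordinates).
#' @return data.frame with columns species, chrom, start, end, strand
#'   (\code{+1}/\code{-1}), family; 0-based half-open coordinates; sorted by
#'   species, chromosome, start.
#' @export
read_gene_orders <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("species", "chrom", "start", "end",
                                        "strand", "family"),
                          colClasses = c("character", "character", "integer",
                                         "integer", "character", "character"))
  if (!all(df$strand %in% c("+", "-"))) stop("malformed strand field in ", path)
  df$sign <- ifelse(df$strand == "+", 1L, -1L)
  df$strand <- NULL
  df$start <- df$start - 1L  # to 0-based half-open
  if (any(df$end - df$start < 1L)) stop("gene occurrence with end <= start in ", path)
  check_ids(df$family, "family id")
  ord <- order(df$species, df$chrom, df$start)
  if (!identical(ord, seq_len(nrow(df)))) {
    warning("gene orders were not coordinate-sorted; sorting")
    df <- df[ord, ]
  }
  rownames(df) <- NULL
  df$occ <- seq_len(nrow(df))
  df
}

#' Read synteny block occurrences
#'
#' @param path BED-like TSV with a leading species column: species,
#'   chromosome, start, end, block, score (ignored), strand.  Coordinates
#'   are 0-based half-open.
#' @return data.frame with columns species, chrom, start, end, block, sign.
#' @export
read_blocks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("species", "chrom", "start", "end",
                                        "block", "score", "strand"),
                          colClasses = c("character", "character", "integer",
                                         "integer", "character", "character",
                                         "character"))
  if (!all(df$strand %in% c("+", "-"))) stop("malformed strand field in ", path)
  df$sign <- ifelse(df$strand == "+", 1L, -1L)
  df$strand <- NULL
  df$score <- NULL
  check_ids(df$block, "block id")
  dup <- duplicated(df[, c("species", "block")])
  if (any(dup)) stop("block occurs more than once in a species: ",
                     paste(unique(df$block[dup]), collapse = ", "))
  df <- df[order(df$species, df$chrom, df$start), ]
  # block occurrences must not overlap within a chromosome
  by_chr <- split(df, paste(df$species, df$chrom))
  for (b in by_chr) {
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      stop("overlapping block occurrences on ", b$species[1], " ", b$chrom[1])
    }
  }
  rownames(df) <- NULL
  df
}

#' Read contiguous ancestral regions (CARs)
#'
#' Each CAR line of signed block ids is expanded into a sequence of block
#' extremities: \code{+b} becomes (b.t, b.h) and \code{-b} becomes
#' (b.h, b.t).
#'
#' @param path CAR text file.
#' @return list of character vectors of extremity keys, one per CAR, named
#'   \code{CAR1}, \code{CAR2}, ...
#' @export
read_cars <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cars <- lapply(lines, function(ln) {
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    signs <- ifelse(startsWith(toks, "-"), -1L, 1L)
    ids <- sub("^[+-]", "", toks)
    check_ids(ids, "block id")
    ext <- character(2 * length(ids))
    ext[seq(1, length(ext), 2)] <- marker_key(ids, ifelse(signs == 1, "t", "h"))
    ext[seq(2, length(ext), 2)] <- marker_key(ids, ifelse(signs == 1, "h", "t"))
    ext
  })
  all_ids <- unlist(lapply(cars, function(x) marker_id(x[seq(1, length(x), 2)])))
  if (anyDuplicated(all_ids)) {
    stop("block id repeated within or across CARs: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  names(cars) <- paste0("CAR", seq_along(cars))
  cars
}

#' Write a reconstructed gene order
#'
#' One line per reconstructed path: CAR id, path rank within the CAR, and
#' the signed family sequence.  A sidecar table \code{<path>.psi.tsv} maps
#' each localization to the CAR regions it is associated with.
#'
#' @param result a \code{multires} reconstruction object.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_gene_order <- function(result, path) {
  stopifnot(inherits(result, "multires"))
  con <- file(path, "w")
  on.exit(close(con))
  for (car in names(result$paths)) {
    pl <- result$paths[[car]]
    for (i in seq_along(pl)) {
      p <- pl[[i]]
      seqs <- paste0(ifelse(p$sign == 1, "+", "-"), p$family, collapse = " ")
      writeLines(paste(car, i, seqs, sep = "\t"), con)
    }
  }
  psi <- result$psi
  if (!is.null(psi) && length(psi)) {
    side <- data.frame(localization = rep(names(psi), lengths(psi)),
                       region = unlist(psi, use.names = FALSE))
    utils::write.table(side, paste0(path, ".psi.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write gene orders in the on-disk TSV dialect
#'
#' Inverse of \code{\link{read_gene_orders}} (coordinates converted back to
#' 1-based inclusive).
#'
#' @param genes data.frame as returned by \code{read_gene_orders}.
#' @param path output file.
#' @export
write_gene_orders <- function(genes, path) {
  out <- data.frame(species = genes$species, chrom = genes$chrom,
                    start = genes$start + 1L, end = genes$end,
                    strand = ifelse(genes$sign == 1, "+", "-"),
                    family = genes$family)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write block occurrences in the BED-like dialect
#'
#' @param blocks data.frame as returned by \code{read_blocks}.
#' @param path output file.
#' @export
write_blocks <- function(blocks, path) {
  out <- data.frame(species = blocks$species, chrom = blocks$chrom,
                    start = blocks$start, end = blocks$end,
                    block = blocks$block, score = 0L,
                    strand = ifelse(blocks$sign == 1, "+", "-"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write CARs as signed block lines
#'
#' @param cars list of extremity sequences (as from \code{read_cars}).
#' @param path output file.
#' @export
write_cars <- function(cars, path) {
  lines <- vapply(cars, function(ext) {
    first <- ext[seq(1, length(ext), 2)]
    paste0(ifelse(marker_side(first) == "t", "+", "-"),
           marker_id(first), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration
#'
#' A flat YAML file of key/value pairs mirroring the arguments of
#' \code{\link{multires}} (window, segment, stride, weight_scheme,
#' max_copies, seed, and input paths tree, ancestor, genes, blocks, cars).
#' Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files")
  }
  cfg <- yaml::read_yaml(path)
  known <- c("window", "segment", "stride", "weight_scheme", "max_copies",
             "seed", "tree", "ancestor", "genes", "blocks", "cars", "out")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  cfg
}
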
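# Hand-built fixtures: small trees and block/gene layouts shared by tests.

# 4-leaf tree ((A,B)ANC,(C,D)): the marked ancestor is the MRCA of A and B,
# and exactly 5 leaf pairs straddle it (A-B and all ingroup x outgroup).
fixture_tree4 <- function() {
  species_tree(ape::read.tree(text = "((A:1,B:1)ANC:1,(C:1,D:1):1);"), "ANC")
}

# Build a single-chromosome instance from a per-species layout.
# layout: named list (species -> list of blocks: named list block ->
# character vector of signed gene ids, e.g. c("g1", "-g2")).  Genes are
# laid end to end (length 100, gap 10); blocks tile their genes.
# Gene ids prefixed with "." are placed between blocks (no block).
make_instance <- function(layout) {
  gene_rows <- list()
  block_rows <- list()
  for (sp in names(layout)) {
    pos <- 0L
    for (bname in names(layout[[sp]])) {
      genes <- layout[[sp]][[bname]]
      bstart <- pos
      for (g in genes) {
        sgn <- if (startsWith(g, "-")) -1L else 1L
        fam <- sub("^-", "", g)
        gene_rows[[length(gene_rows) + 1]] <-
          data.frame(species = sp, chrom = "chr1", start = pos,
                     end = pos + 100L, sign = sgn, family = fam)
        pos <- pos + 110L
      }
      if (!startsWith(bname, ".")) {
        block_rows[[length(block_rows) + 1]] <-
          data.frame(species = sp, chrom = "chr1", start = bstart,
                     end = pos - 10L, block = bname, sign = 1L)
      }
    }
  }
  genes <- do.call(rbind, gene_rows)
  genes <- genes[order(genes$species, genes$chrom, genes$start), ]
  rownames(genes) <- NULL
  genes$occ <- seq_len(nrow(genes))
  blocks <- do.call(rbind, block_rows)
  rownames(blocks) <- NULL
  list(genes = genes, blocks = blocks)
}

# CAR over the given blocks, all forward: +b1 +b2 ... as extremities
forward_car <- function(block_ids) {
  ext <- character(2 * length(block_ids))
  ext[seq(1, length(ext), 2)] <- paste0(block_ids, ":t")
  ext[seq(2, length(ext), 2)] <- paste0(block_ids, ":h")
  ext
}

# Schematic worked example: six blocks on one CAR; the "brown" family g1
# occurs once in block b1 and once in block b5 in every species, far
# apart, so windows of length 3 must split it into two localizations.
fixture_two_copy_family <- function() {
  blocks6 <- list(b1 = c("g1", "g2"), b2 = "g3", b3 = "g4",
                  b4 = "g5", b5 = c("g1", "g6"), b6 = "g7")
  layout <- list(A = blocks6, B = blocks6, C = blocks6, D = blocks6)
  inst <- make_instance(layout)
  inst$cars <- list(CAR1 = forward_car(paste0("b", 1:6)))
  inst$tree <- fixture_tree4()
  inst
}

# small deterministic simulation shared by property tests
quick_sim <- function(seed, n_genes = 60, n_families = 50, n_blocks = 10,
                      rate_mult = 1) {
  cfg <- sim_config(n_genes = n_genes, n_families = n_families,
                    n_blocks = n_blocks,
                    inversion_rate = 0.5 * rate_mult,
                    duplication_rate = 0.25 * rate_mult,
                    insertion_rate = 0.1 * rate_mult,
                    deletion_rate = 0.1 * rate_mult)
  sim_genomes(mammalian_tree(), cfg, seed = seed)
}
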
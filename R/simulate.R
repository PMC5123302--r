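# Genome-evolution simulator.
#
# A root genome of genes grouped into contiguous synteny blocks evolves
# along the species tree by inversions, duplications (tandem with a
# configurable fraction), insertions of novel genes, and deletions.
# Per-branch event counts are Poisson with mean rate * branch length.  The
# genome recorded at the marked ancestor is the ground truth; leaves are
# laid out with fixed-size gene loci, block occurrences are recomputed
# from the block memberships of the surviving genes, and CARs are emitted
# from the true ancestral block order (optionally split to mimic a
# fragmented synteny-level reconstruction).
#
# Duplicated gene copies do not inherit the block tag of their source (a
# duplicated segment is not part of the syntenic occurrence of its block),
# which preserves the at-most-one-occurrence-per-species block invariant;
# a duplication that would copy every remaining gene of some block is
# resampled.

#' Simulation configuration
#'
#' Event rates are per unit branch length.  The defaults correspond to the
#' "low" rearrangement preset at full scale: ~730 genes in ~630 families
#' grouped into 150 blocks on one chromosome.
#'
#' @param n_genes number of genes in the root genome.
#' @param n_families number of distinct families at the root (the excess
#'   \code{n_genes - n_families} genes are duplicate copies already present
#'   at the root).
#' @param n_blocks number of synteny blocks partitioning the root genome.
#' @param inversion_rate,duplication_rate,insertion_rate,deletion_rate
#'   expected event counts per unit branch length.
#' @param tandem_fraction probability that a duplication is tandem.
#' @param inv_len_mean,dup_len_mean,del_len_mean mean event lengths in
#'   genes (geometric).
#' @param gene_length,gene_gap base-pair layout of emitted leaf genomes.
#' @param fragments number of pieces the true ancestral block order is
#'   split into when emitting CARs (1 = one CAR per ancestral chromosome).
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 730, n_families = 630, n_blocks = 150,
                       inversion_rate = 3, duplication_rate = 1.2,
                       insertion_rate = 0.6, deletion_rate = 0.6,
                       tandem_fraction = 0.4,
                       inv_len_mean = 5, dup_len_mean = 2, del_len_mean = 2,
                       gene_length = 1000L, gene_gap = 100L,
                       fragments = 1L) {
  stopifnot(n_families <= n_genes, n_blocks <= n_families,
            inversion_rate >= 0, duplication_rate >= 0,
            insertion_rate >= 0, deletion_rate >= 0,
            tandem_fraction >= 0, tandem_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulation presets
#'
#' The \code{"low"} and \code{"high"} presets differ by a factor 3 on all
#' event rates; they bracket a mildly and a heavily rearranged history at
#' the ~730-gene scale.
#'
#' @param preset \code{"low"} or \code{"high"}.
#' @param ... overrides passed to \code{\link{sim_config}}.
#' @return a \code{sim_config}.
#' @export
sim_preset <- function(preset = c("low", "high"), ...) {
  preset <- match.arg(preset)
  base <- list(low = list(), high = list(inversion_rate = 9,
                                         duplication_rate = 3.6,
                                         insertion_rate = 1.8,
                                         deletion_rate = 1.8))[[preset]]
  do.call(sim_config, utils::modifyList(base, list(...)))
}

#' Default mammalian species tree
#'
#' Ten species (six ingroups: human, chimpanzee, macaque, marmoset, mouse,
#' rat; four outgroups: dog, horse, cattle, pig) with unit branch lengths
#' and the primate-rodent most recent common ancestor marked.
#'
#' @return a \code{multires_tree}.
#' @export
mammalian_tree <- function() {
  nwk <- paste0("(((((human:1,chimpanzee:1):1,macaque:1):1,marmoset:1):1,",
                "(mouse:1,rat:1):1)ANC:1,",
                "((dog:1,horse:1):1,(cattle:1,pig:1):1):1);")
  species_tree(ape::read.tree(text = nwk), "ANC")
}

# ---- genome representation during simulation -------------------------------
# A chromosome is a data.frame: family, sign, block (NA for genes with no
# syntenic membership), bpos (root position within the block), rsign (root
# sign).  A genome is a list of chromosomes.

root_genome <- function(cfg) {
  fams <- paste0("f", seq_len(cfg$n_families))
  order0 <- sample(fams)
  extra <- cfg$n_genes - cfg$n_families
  if (extra > 0) {
    src <- sample(seq_along(order0), extra, replace = TRUE)
    seqs <- order0
    for (s in sort(src, decreasing = TRUE)) {
      seqs <- append(seqs, seqs[s], after = s)
    }
    order0 <- seqs
  }
  n <- length(order0)
  sizes <- rep(n %/% cfg$n_blocks, cfg$n_blocks)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  block <- rep(paste0("b", seq_len(cfg$n_blocks)), times = sizes)
  bpos <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  sign <- sample(c(-1L, 1L), n, replace = TRUE)
  chr <- data.frame(family = order0, sign = sign, block = block,
                    bpos = bpos, rsign = sign)
  list(chr1 = chr)
}

# ---- event application -----------------------------------------------------

apply_inversion <- function(chr, i, len) {
  j <- min(nrow(chr), i + len - 1L)
  seg <- chr[i:j, , drop = FALSE]
  seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
  seg$sign <- -seg$sign
  chr[i:j, ] <- seg
  chr
}

apply_duplication <- function(chr, i, len, at) {
  j <- min(nrow(chr), i + len - 1L)
  seg <- chr[i:j, , drop = FALSE]
  seg$block <- NA_character_
  seg$bpos <- NA_integer_
  top <- chr[seq_len(at), , drop = FALSE]
  bot <- if (at < nrow(chr)) chr[(at + 1):nrow(chr), , drop = FALSE] else chr[0, ]
  out <- rbind(top, seg, bot)
  rownames(out) <- NULL
  out
}

apply_insertion <- function(chr, at, fam, sign) {
  row <- data.frame(family = fam, sign = sign, block = NA_character_,
                    bpos = NA_integer_, rsign = sign)
  top <- chr[seq_len(at), , drop = FALSE]
  bot <- if (at < nrow(chr)) chr[(at + 1):nrow(chr), , drop = FALSE] else chr[0, ]
  out <- rbind(top, row, bot)
  rownames(out) <- NULL
  out
}

apply_deletion <- function(chr, i, len) {
  j <- min(nrow(chr), i + len - 1L)
  if (j - i + 1L >= nrow(chr)) stop("deletion would empty the chromosome")
  out <- chr[-(i:j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# would copying run [i, j] of chr remove block uniqueness (i.e. cover every
# remaining gene of some block)?
covers_whole_block <- function(chr, i, j) {
  tags <- chr$block[i:j]
  tags <- unique(tags[!is.na(tags)])
  for (b in tags) {
    if (sum(chr$block == b, na.rm = TRUE) == sum(chr$block[i:j] == b, na.rm = TRUE)) {
      return(TRUE)
    }
  }
  FALSE
}

rgeom_len <- function(mean_len) {
  if (mean_len <= 1) return(1L)
  1L + stats::rgeom(1, 1 / mean_len)
}

# Evolve one genome along one branch; returns list(genome, log).
evolve_branch <- function(genome, cfg, branch_len, counter_env) {
  counts <- c(inv = stats::rpois(1, cfg$inversion_rate * branch_len),
              dup = stats::rpois(1, cfg$duplication_rate * branch_len),
              ins = stats::rpois(1, cfg$insertion_rate * branch_len),
              del = stats::rpois(1, cfg$deletion_rate * branch_len))
  types <- sample(rep(names(counts), counts))
  log <- list()
  for (tp in types) {
    ci <- if (length(genome) == 1) 1L else {
      sample(seq_along(genome), 1, prob = vapply(genome, nrow, numeric(1)))
    }
    chr <- genome[[ci]]
    n <- nrow(chr)
    ev <- switch(tp,
      inv = {
        len <- rgeom_len(cfg$inv_len_mean)
        i <- sample.int(n, 1)
        genome[[ci]] <- apply_inversion(chr, i, len)
        list(type = "inv", chrom = ci, i = i, len = len)
      },
      dup = {
        len <- rgeom_len(cfg$dup_len_mean)
        ok <- FALSE
        i <- NA
        for (try in 1:10) {
          i <- sample.int(n, 1)
          j <- min(n, i + len - 1L)
          if (!covers_whole_block(chr, i, j)) { ok <- TRUE; break }
        }
        if (!ok) { NULL } else {
          at <- if (stats::runif(1) < cfg$tandem_fraction) {
            min(n, i + len - 1L)
          } else {
            sample.int(n + 1L, 1) - 1L
          }
          genome[[ci]] <- apply_duplication(chr, i, len, at)
          list(type = "dup", chrom = ci, i = i, len = len, at = at)
        }
      },
      ins = {
        counter_env$ins <- counter_env$ins + 1L
        fam <- paste0("n", counter_env$ins)
        at <- sample.int(n + 1L, 1) - 1L
        sgn <- sample(c(-1L, 1L), 1)
        genome[[ci]] <- apply_insertion(chr, at, fam, sgn)
        list(type = "ins", chrom = ci, at = at, fam = fam, sign = sgn)
      },
      del = {
        if (n <= 1) stop("deletion rate empties the genome")
        len <- min(rgeom_len(cfg$del_len_mean), n - 1L)
        i <- sample.int(n - len + 1L, 1)
        genome[[ci]] <- apply_deletion(chr, i, len)
        list(type = "del", chrom = ci, i = i, len = len)
      })
    if (!is.null(ev)) log[[length(log) + 1]] <- ev
  }
  list(genome = genome, log = log)
}

# Deterministic replay of a recorded branch log.
replay_branch <- function(genome, log) {
  for (ev in log) {
    chr <- genome[[ev$chrom]]
    genome[[ev$chrom]] <- switch(ev$type,
      inv = apply_inversion(chr, ev$i, ev$len),
      dup = apply_duplication(chr, ev$i, ev$len, ev$at),
      ins = apply_insertion(chr, ev$at, ev$fam, ev$sign),
      del = apply_deletion(chr, ev$i, ev$len))
  }
  genome
}

# ---- leaf layout -----------------------------------------------------------

# block runs of a chromosome: maximal stretches of genes sharing a block
# tag, ignoring interleaved untagged genes.  Returns data.frame: block,
# from, to (gene indices of the first/last tagged gene), ngenes, sign.
block_runs <- function(chr) {
  tagged <- which(!is.na(chr$block))
  if (length(tagged) == 0) {
    return(data.frame(block = character(0), from = integer(0),
                      to = integer(0), ngenes = integer(0), sign = integer(0)))
  }
  tags <- chr$block[tagged]
  r <- rle(tags)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  runs <- data.frame(block = r$values,
                     from = tagged[starts], to = tagged[stops],
                     ngenes = r$lengths)
  runs$sign <- vapply(seq_len(nrow(runs)), function(k) {
    idx <- tagged[starts[k]:stops[k]]
    if (length(idx) >= 2) {
      if (chr$bpos[idx[1]] < chr$bpos[idx[length(idx)]]) 1L else -1L
    } else {
      if (chr$sign[idx] == chr$rsign[idx]) 1L else -1L
    }
  }, integer(1))
  runs
}

# one occurrence per block: the run with the most genes (ties: leftmost)
choose_block_occurrences <- function(chr) {
  runs <- block_runs(chr)
  if (nrow(runs) == 0) return(runs)
  runs <- runs[order(runs$block, -runs$ngenes, runs$from), ]
  runs <- runs[!duplicated(runs$block), ]
  runs[order(runs$from), ]
}

layout_coords <- function(n, cfg) {
  start <- (seq_len(n) - 1L) * (cfg$gene_length + cfg$gene_gap)
  cbind(start = start, end = start + cfg$gene_length)
}

# signed block order of a genome (for truth CARs)
genome_block_order <- function(genome) {
  lapply(genome, function(chr) {
    runs <- choose_block_occurrences(chr)
    if (nrow(runs) == 0) return(data.frame(block = character(0), sign = integer(0)))
    runs[, c("block", "sign")]
  })
}

# ---- main entry ------------------------------------------------------------

#' Simulate genome evolution along a species tree
#'
#' @param tree a \code{multires_tree}; defaults to \code{mammalian_tree()}.
#' @param cfg a \code{sim_config}.
#' @param seed integer random seed (reproducible).
#' @return object of class \code{multires_sim}: list with \code{genes}
#'   (leaf gene-order data.frame in the internal layout), \code{blocks}
#'   (leaf block occurrences), \code{cars} (CARs from the true ancestral
#'   block order), \code{ancestor} (true ancestral genome: list of
#'   data.frames family/sign), \code{truth_adj} (true ancestral adjacency
#'   multiset), \code{truth_mu} (true ancestral copy numbers),
#'   \code{genomes} (full per-leaf genomes), \code{logs} (per-branch event
#'   logs), \code{tree}, \code{cfg}.
#' @export
sim_genomes <- function(tree = mammalian_tree(), cfg = sim_config(), seed = 1) {
  set.seed(seed)
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  counter_env <- new.env(parent = emptyenv())
  counter_env$ins <- 0L
  genomes <- vector("list", ntip + phy$Nnode)
  logs <- list()
  root <- ntip + 1L
  genomes[[root]] <- root_genome(cfg)
  # preorder traversal: parents before children
  po <- rev(ape::postorder(phy))
  for (e in po) {
    par <- phy$edge[e, 1]; child <- phy$edge[e, 2]
    res <- evolve_branch(genomes[[par]], cfg, phy$edge.length[e], counter_env)
    genomes[[child]] <- res$genome
    logs[[paste(par, child, sep = "->")]] <- res$log
  }
  anc_genome <- genomes[[tree$ancestor]]
  ancestor <- lapply(anc_genome, function(chr) chr[, c("family", "sign")])
  truth_adj <- genome_adjacencies(ancestor)
  truth_mu <- table(unlist(lapply(ancestor, `[[`, "family")))
  truth_mu <- stats::setNames(as.integer(truth_mu), names(truth_mu))
  # leaf outputs
  gene_rows <- list()
  block_rows <- list()
  for (li in seq_len(ntip)) {
    sp <- phy$tip.label[li]
    for (cn in names(genomes[[li]])) {
      chr <- genomes[[li]][[cn]]
      xy <- layout_coords(nrow(chr), cfg)
      gene_rows[[length(gene_rows) + 1]] <-
        data.frame(species = sp, chrom = cn, start = xy[, "start"],
                   end = xy[, "end"], sign = chr$sign, family = chr$family)
      occ <- choose_block_occurrences(chr)
      if (nrow(occ)) {
        block_rows[[length(block_rows) + 1]] <-
          data.frame(species = sp, chrom = cn,
                     start = xy[occ$from, "start"], end = xy[occ$to, "end"],
                     block = occ$block, sign = occ$sign)
      }
    }
  }
  genes <- do.call(rbind, gene_rows)
  genes <- genes[order(genes$species, genes$chrom, genes$start), ]
  rownames(genes) <- NULL
  genes$occ <- seq_len(nrow(genes))
  blocks <- do.call(rbind, block_rows)
  blocks <- blocks[order(blocks$species, blocks$chrom, blocks$start), ]
  rownames(blocks) <- NULL
  # CARs from the true ancestral block order
  cars <- list()
  for (bo in genome_block_order(anc_genome)) {
    if (nrow(bo) == 0) next
    pieces <- if (cfg$fragments > 1) {
      cut_idx <- sort(sample.int(nrow(bo) - 1L, min(cfg$fragments - 1L, nrow(bo) - 1L)))
      split(seq_len(nrow(bo)), findInterval(seq_len(nrow(bo)), cut_idx + 1L) + 1L)
    } else {
      list(seq_len(nrow(bo)))
    }
    for (p in pieces) {
      sub <- bo[p, , drop = FALSE]
      ext <- character(2 * nrow(sub))
      ext[seq(1, length(ext), 2)] <- marker_key(sub$block, ifelse(sub$sign == 1, "t", "h"))
      ext[seq(2, length(ext), 2)] <- marker_key(sub$block, ifelse(sub$sign == 1, "h", "t"))
      cars[[length(cars) + 1]] <- ext
    }
  }
  names(cars) <- paste0("CAR", seq_along(cars))
  structure(list(genes = genes, blocks = blocks, cars = cars,
                 ancestor = ancestor, truth_adj = truth_adj,
                 truth_mu = truth_mu, genomes = genomes[seq_len(ntip)],
                 node_genomes = genomes, logs = logs,
                 tree = tree, cfg = cfg, seed = seed),
            class = "multires_sim")
}

#' @export
print.multires_sim <- function(x, ...) {
  cat(sprintf("Simulated data set: %d leaf species, %d ancestral genes (%d families), %d CARs\n",
              length(unique(x$genes$species)),
              sum(vapply(x$ancestor, nrow, integer(1))),
              length(x$truth_mu), length(x$cars)))
  invisible(x)
}

#' Breakpoint count between two genomes
#'
#' The number of adjacencies of genome \code{a} absent from genome
#' \code{b}, on the doubled marker representation, with duplicates matched
#' as multisets.
#'
#' @param genome_a,genome_b genomes as lists of data.frames (family, sign).
#' @return integer.
#' @export
breakpoint_count <- function(genome_a, genome_b) {
  ta <- table(genome_adjacencies(genome_a))
  tb <- table(genome_adjacencies(genome_b))
  common <- intersect(names(ta), names(tb))
  sum(ta) - sum(pmin(ta[common], tb[common]))
}

#' Calibrate event rates to a target breakpoint count
#'
#' Bisection on a global rate multiplier until the mean pairwise
#' breakpoint count between ingroup leaves falls inside the target
#' interval.
#'
#' @param tree a \code{multires_tree}.
#' @param cfg base \code{sim_config}.
#' @param target length-2 numeric interval of mean ingroup pairwise
#'   breakpoints.
#' @param seed seed used for the trial simulations.
#' @param max_iter bisection iterations.
#' @return the calibrated \code{sim_config}.
#' @export
calibrate_rates <- function(tree, cfg, target, seed = 1, max_iter = 12) {
  stopifnot(length(target) == 2, target[1] <= target[2])
  scale_cfg <- function(m) {
    c2 <- cfg
    for (f in c("inversion_rate", "duplication_rate", "insertion_rate",
                "deletion_rate")) c2[[f]] <- cfg[[f]] * m
    class(c2) <- "sim_config"
    c2
  }
  measure <- function(m) {
    sim <- sim_genomes(tree, scale_cfg(m), seed = seed)
    mean_ingroup_breakpoints(sim)
  }
  lo <- 0.05; hi <- 1
  while (measure(hi) < target[1] && hi < 64) hi <- hi * 2
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    b <- measure(mid)
    if (b >= target[1] && b <= target[2]) return(scale_cfg(mid))
    if (b < target[1]) lo <- mid else hi <- mid
  }
  scale_cfg(sqrt(lo * hi))
}

# mean pairwise breakpoint count between ingroup leaves (descendants of
# the marked ancestor)
mean_ingroup_breakpoints <- function(sim) {
  phy <- sim$tree$phylo
  ntip <- length(phy$tip.label)
  desc <- ingroup_leaves(sim$tree)
  idx <- match(desc, phy$tip.label)
  if (length(idx) < 2) return(NA_real_)
  cmb <- utils::combn(idx, 2)
  mean(vapply(seq_len(ncol(cmb)), function(j) {
    ga <- lapply(sim$genomes[[cmb[1, j]]], function(c) c[, c("family", "sign")])
    gb <- lapply(sim$genomes[[cmb[2, j]]], function(c) c[, c("family", "sign")])
    as.numeric(breakpoint_count(ga, gb))
  }, numeric(1)))
}

# leaves descending from the marked ancestor
ingroup_leaves <- function(tree) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  kids <- tree$ancestor
  out <- integer(0)
  repeat {
    newk <- phy$edge[phy$edge[, 1] %in% kids, 2]
    tips <- newk[newk <= ntip]
    out <- c(out, tips)
    kids <- newk[newk > ntip]
    if (length(kids) == 0) break
  }
  phy$tip.label[sort(unique(out))]
}
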
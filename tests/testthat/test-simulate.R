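test_that("simulation is reproducible from its seed", {
  s1 <- quick_sim(9)
  s2 <- quick_sim(9)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$blocks, s2$blocks)
  expect_identical(s1$cars, s2$cars)
  expect_identical(s1$ancestor, s2$ancestor)
  s3 <- quick_sim(10)
  expect_false(identical(s1$genes, s3$genes))
})

test_that("zero rates propagate the root genome unchanged", {
  cfg <- sim_config(n_genes = 40, n_families = 35, n_blocks = 8,
                    inversion_rate = 0, duplication_rate = 0,
                    insertion_rate = 0, deletion_rate = 0)
  sim <- sim_genomes(mammalian_tree(), cfg, seed = 2)
  root_fams <- sim$ancestor[[1]]$family
  for (g in sim$genomes) {
    expect_identical(g[[1]]$family, root_fams)
    expect_identical(g[[1]]$sign, sim$ancestor[[1]]$sign)
  }
  expect_equal(breakpoint_count(sim$ancestor,
                                lapply(sim$genomes[[1]], `[`, c("family", "sign"))), 0)
})

test_that("event-log replay reconstructs every leaf from its parent", {
  sim <- quick_sim(13, rate_mult = 2)
  phy <- sim$tree$phylo
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]; child <- phy$edge[e, 2]
    log <- sim$logs[[paste(par, child, sep = "->")]]
    replayed <- replay_branch(sim$node_genomes[[par]], log)
    expect_identical(replayed, sim$node_genomes[[child]],
                     info = paste("edge", par, "->", child))
  }
})

test_that("a single inversion creates two breakpoints against the parent", {
  cfg <- sim_config(n_genes = 30, n_families = 30, n_blocks = 5,
                    inversion_rate = 0, duplication_rate = 0,
                    insertion_rate = 0, deletion_rate = 0)
  sim <- sim_genomes(mammalian_tree(), cfg, seed = 3)
  chr <- sim$ancestor[[1]]
  set.seed(4)
  inverted <- apply_inversion(cbind(chr, block = NA, bpos = NA, rsign = chr$sign),
                              i = 10L, len = 5L)
  expect_equal(breakpoint_count(list(chr), list(inverted[, c("family", "sign")])), 2)
})

test_that("duplication-only evolution never loses family copies", {
  cfg <- sim_config(n_genes = 40, n_families = 35, n_blocks = 8,
                    inversion_rate = 0, duplication_rate = 1,
                    insertion_rate = 0, deletion_rate = 0)
  sim <- sim_genomes(mammalian_tree(), cfg, seed = 5)
  root_counts <- table(sim$node_genomes[[11]][[1]]$family)
  for (g in sim$genomes) {
    leaf_counts <- table(g[[1]]$family)
    expect_true(all(leaf_counts[names(root_counts)] >= root_counts))
  }
})

test_that("leaf block occurrences are unique, disjoint and strand-aware", {
  sim <- quick_sim(17, rate_mult = 3)
  b <- sim$blocks
  expect_false(any(duplicated(paste(b$species, b$block))))
  for (sp in unique(b$species)) {
    bs <- b[b$species == sp, ]
    bs <- bs[order(bs$start), ]
    if (nrow(bs) > 1) {
      expect_true(all(bs$start[-1] >= bs$end[-nrow(bs)]))
    }
  }
})

test_that("rate calibration hits a target breakpoint interval", {
  cfg <- sim_config(n_genes = 60, n_families = 50, n_blocks = 10,
                    inversion_rate = 2, duplication_rate = 0.8,
                    insertion_rate = 0.4, deletion_rate = 0.4)
  cal <- calibrate_rates(mammalian_tree(), cfg, target = c(10, 30), seed = 6)
  sim <- sim_genomes(mammalian_tree(), cal, seed = 6)
  bp <- mean_ingroup_breakpoints(sim)
  expect_gte(bp, 10)
  expect_lte(bp, 30)
})
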
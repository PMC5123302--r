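test_that("adjacencies are conserved only with a straddling species pair", {
  tr <- mammalian_tree()
  # one chromosome per species: g1 g2 g3; mouse shares g1-g2 with human,
  # chimp shares g2-g3 with human only among non-straddling species
  mk <- function(sp, fams) {
    data.frame(species = sp, chrom = "c", start = seq_along(fams) * 100L,
               end = seq_along(fams) * 100L + 50L, sign = 1L, family = fams)
  }
  genes <- rbind(mk("human", c("g1", "g2", "g3")),
                 mk("mouse", c("g1", "g2", "g4")),
                 mk("chimpanzee", c("g5", "g2", "g3")))
  genes$occ <- seq_len(nrow(genes))
  cons <- conserved_adjacencies(genes, tr)
  # g1-g2 seen in human and mouse (ancestor on path) -> conserved
  expect_true("g1:h--g2:t" %in% cons$edges)
  # g2-g3 seen in human and chimpanzee only (path avoids ancestor) -> not
  expect_false("g2:h--g3:t" %in% cons$edges)
  ev <- cons$evidence[["g1:h--g2:t"]]
  expect_true(all(apply(ev, 1, function(p) ancestor_on_path(tr, p[1], p[2]))))
})

test_that("pair-count weight is supporting pairs over possible pairs", {
  tr <- fixture_tree4()
  # straddling pairs of ((A,B)ANC,(C,D)): A-B, A-C, A-D, B-C, B-D = 5
  expect_equal(nrow(straddling_pairs(tr)), 5)
  expect_equal(adjacency_weight(rbind(c("A", "B")), tr, "pair-count"), 1 / 5)
  allp <- straddling_pairs(tr)
  expect_equal(adjacency_weight(allp, tr, "pair-count"), 1)
  expect_error(adjacency_weight(matrix(character(0), ncol = 2), tr), "empty")
})

test_that("branch-decay weight is max exp(-distance) over supporting pairs", {
  tr <- fixture_tree4()
  # d(A,B) = 2 with unit branches; d(A,C) = 4
  expect_equal(adjacency_weight(rbind(c("A", "B")), tr, "branch-decay"), exp(-2))
  expect_equal(adjacency_weight(rbind(c("A", "C"), c("A", "B")), tr,
                                "branch-decay"), exp(-2))
})

test_that("ancestral copy number matches exhaustive small parsimony", {
  tr <- mammalian_tree()
  lv <- tree_leaves(tr)
  # constant counts are returned unchanged
  expect_equal(ancestral_copy_number(stats::setNames(rep(1L, 10), lv), tr), 1)
  ing <- ingroup_leaves(tr)
  outg <- setdiff(lv, ing)
  counts <- stats::setNames(ifelse(lv %in% ing, 2L, 1L), lv)
  expect_equal(ancestral_copy_number(counts, tr),
               oracle_ancestral_count(counts, tr))
  expect_equal(ancestral_copy_number(counts, tr), 2)
  one_out <- stats::setNames(1L, outg[1])
  expect_equal(ancestral_copy_number(one_out, tr),
               oracle_ancestral_count(one_out, tr))
  expect_equal(ancestral_copy_number(one_out, tr), 0)
  expect_error(ancestral_copy_number(integer(0), tr), "absent")
})

test_that("Sankoff equals brute force on random leaf counts", {
  tr4 <- fixture_tree4()
  tr10 <- mammalian_tree()
  set.seed(7)
  for (rep in 1:25) {
    tr <- if (rep %% 2 == 0) tr4 else tr10
    lv <- tree_leaves(tr)
    counts <- stats::setNames(sample(0:4, length(lv), replace = TRUE), lv)
    if (all(counts == 0)) counts[1] <- 1L
    expect_equal(ancestral_copy_number(counts, tr),
                 oracle_ancestral_count(counts, tr),
                 info = paste("rep", rep))
  }
})

test_that("family filter is a strict cap and idempotent", {
  genes <- data.frame(species = "A", chrom = "c",
                      start = c(0L, 100L, 200L), end = c(50L, 150L, 250L),
                      sign = 1L, family = c("f1", "f2", "f3"),
                      occ = 1:3)
  mu <- c(f1 = 16L, f2 = 15L, f3 = 1L)
  out <- filter_families(genes, mu, cap = 15)
  expect_identical(out$family, c("f2", "f3"))
  expect_identical(filter_families(out, mu, cap = 15), out)
  expect_identical(filter_families(genes, mu, cap = Inf), genes)
})

test_that("marker graph carries weighted adjacency and pairing edges", {
  tr <- fixture_tree4()
  mk <- function(sp) {
    data.frame(species = sp, chrom = "c", start = c(0L, 100L),
               end = c(50L, 150L), sign = 1L, family = c("g1", "g2"))
  }
  genes <- rbind(mk("A"), mk("C"))
  genes$occ <- seq_len(nrow(genes))
  cons <- conserved_adjacencies(genes, tr)
  g <- build_marker_adjacency_graph(cons, c(g1 = 1L, g2 = 1L), tr)
  adj <- g$edges[g$edges$type == "adjacency", ]
  expect_identical(adj$key, "g1:h--g2:t")
  expect_equal(adj$weight, 1 / 5)
  expect_setequal(g$edges$key[g$edges$type == "pairing"],
                  c("g1:h--g1:t", "g2:h--g2:t"))
})
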
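test_that("window enumeration slides at stride 1 over extremities", {
  car <- forward_car(c("b1", "b2", "b3"))  # 6 extremities
  ws <- enumerate_windows(car, 3)
  expect_length(ws, 4)
  expect_identical(ws[[1]]$regions,
                   c(region_key("b1:t", "b1:h"), region_key("b1:h", "b2:t")))
  expect_length(enumerate_windows(car, 6), 1)
  expect_error(enumerate_windows(car, 2), ">= 3")
  expect_error(enumerate_windows(car, 7), "exceeds")
})

test_that("a family seen in two distant regions splits into two localizations", {
  inst <- fixture_two_copy_family()
  regions <- extant_regions(inst$blocks)
  ct <- containment_table(inst$genes, regions)
  mu <- ancestral_copy_numbers(inst$genes, inst$tree)
  expect_equal(unname(mu["g1"]), 2)
  lset <- build_localizations(inst$genes, inst$tree, inst$cars, ct, mu,
                              window = 3)
  g1_locs <- names(lset$locs)[vapply(lset$locs, function(l) l$family == "g1",
                                     logical(1))]
  expect_length(g1_locs, 2)
  # psi sets are disjoint and separate the b1 copy from the b5 copy
  psi <- lset$psi[g1_locs]
  expect_length(intersect(psi[[1]], psi[[2]]), 0)
  blocks_of <- function(p) unique(marker_id(unlist(region_extremities(p))))
  expect_setequal(unlist(lapply(psi, blocks_of)), c("b1", "b5"))
})

test_that("one region or one shared window yields a single localization", {
  inst <- fixture_two_copy_family()
  regions <- extant_regions(inst$blocks)
  ct <- containment_table(inst$genes, regions)
  mu <- ancestral_copy_numbers(inst$genes, inst$tree)
  lset <- build_localizations(inst$genes, inst$tree, inst$cars, ct, mu,
                              window = 3)
  for (fam in c("g2", "g3", "g6")) {
    locs <- names(lset$locs)[vapply(lset$locs, function(l) l$family == fam,
                                    logical(1))]
    expect_length(locs, 1)
  }
  # with a window long enough to span both copies, the family must not split
  lset_wide <- build_localizations(inst$genes, inst$tree, inst$cars, ct, mu,
                                   window = 12)
  g1_wide <- names(lset_wide$locs)[vapply(lset_wide$locs,
                                          function(l) l$family == "g1",
                                          logical(1))]
  expect_length(g1_wide, 1)
})

test_that("copy-number rebalancing deletes then decrements deterministically", {
  # two localizations (2,1), family copy number 2 -> the max is decremented
  mu1 <- rebalance_copy_numbers(c(`f@1` = 2L, `f@2` = 1L), 2L,
                                degree = c(`f@1` = 1L, `f@2` = 1L),
                                psi_pos = c(`f@1` = 1, `f@2` = 5))
  expect_identical(mu1, c(`f@1` = 1L, `f@2` = 1L))
  # zero-degree localization is deleted first, survivor decremented
  mu2 <- rebalance_copy_numbers(c(`f@1` = 3L, `f@2` = 1L), 1L,
                                degree = c(`f@1` = 2L, `f@2` = 0L),
                                psi_pos = c(`f@1` = 1, `f@2` = 5))
  expect_identical(mu2, c(`f@1` = 1L))
  # already balanced input is untouched
  mu3 <- rebalance_copy_numbers(c(`f@1` = 1L, `f@2` = 1L), 2L,
                                degree = c(`f@1` = 1L, `f@2` = 1L),
                                psi_pos = c(`f@1` = 1, `f@2` = 5))
  expect_identical(mu3, c(`f@1` = 1L, `f@2` = 1L))
  # tie at the max: the localization whose region lies rightmost loses
  mu4 <- rebalance_copy_numbers(c(`f@1` = 2L, `f@2` = 2L), 3L,
                                degree = c(`f@1` = 1L, `f@2` = 1L),
                                psi_pos = c(`f@1` = 1, `f@2` = 5))
  expect_identical(mu4, c(`f@1` = 2L, `f@2` = 1L))
  # every localization deleted -> empty result (family dropped upstream)
  mu5 <- rebalance_copy_numbers(c(`f@1` = 1L), 1L, degree = c(`f@1` = 0L),
                                psi_pos = c(`f@1` = 1))
  expect_length(mu5, 0)
})

test_that("localized adjacencies re-attach to the right localizations", {
  inst <- fixture_two_copy_family()
  regions <- extant_regions(inst$blocks)
  ct <- containment_table(inst$genes, regions)
  mu <- ancestral_copy_numbers(inst$genes, inst$tree)
  cons <- conserved_adjacencies(inst$genes, inst$tree)
  mg <- build_marker_adjacency_graph(cons, mu, inst$tree)
  lset <- build_localizations(inst$genes, inst$tree, inst$cars, ct, mu,
                              window = 3)
  led <- localize_adjacencies(mg, lset, inst$genes, ct, inst$tree)
  # the two g1 copies carry disjoint adjacency neighbourhoods: the b1 copy
  # joins g2, the b5 copy joins g5 and g6
  nb <- function(loc) {
    hit <- grepl(paste0("^", loc, ":"), led$u) | grepl(paste0("^", loc, ":"), led$v)
    unique(loc_family(c(sub(":[ht]$", "", led$u[hit]), sub(":[ht]$", "", led$v[hit]))))
  }
  g1_locs <- sort(names(lset$locs)[vapply(lset$locs, function(l) l$family == "g1",
                                          logical(1))])
  nbs <- lapply(g1_locs, nb)
  expect_setequal(unlist(nbs), c("g1", "g2", "g5", "g6"))
  expect_length(intersect(setdiff(nbs[[1]], "g1"), setdiff(nbs[[2]], "g1")), 0)
})

test_that("localization copy numbers conserve the family copy number", {
  for (seed in 1:3) {
    sim <- quick_sim(seed)
    genes <- sim$genes
    tree <- sim$tree
    regions <- extant_regions(sim$blocks)
    ct <- containment_table(genes, regions)
    mu <- ancestral_copy_numbers(genes, tree)
    mu <- mu[mu > 0]
    lset <- build_localizations(genes, tree, sim$cars, ct, mu, window = 5)
    cons <- conserved_adjacencies(genes, tree)
    mg <- build_marker_adjacency_graph(cons, mu, tree)
    led <- localize_adjacencies(mg, lset, genes, ct, tree)
    mu0 <- initial_loc_mu(lset, ct, mu, tree)
    mu_loc <- suppressWarnings(rebalance_all(lset, mu0, mu, led))
    sums <- tapply(mu_loc, loc_family(names(mu_loc)), sum)
    expect_true(all(sums == mu[names(sums)]))
    # psi disjointness within every family
    psi <- lset$psi
    fams <- split(names(psi), vapply(lset$locs, `[[`, character(1), "family"))
    for (f in fams) {
      rs <- unlist(psi[f])
      expect_true(!anyDuplicated(rs))
    }
  }
})
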
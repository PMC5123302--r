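test_that("segment enumeration covers the CAR with an anchored tail", {
  car8 <- forward_car(paste0("b", 1:4))  # 8 extremities
  segs <- enumerate_segments(car8, 4, stride = 2)
  expect_equal(vapply(segs, `[[`, integer(1), "start"), c(1L, 3L, 5L))
  expect_length(segs[[1]]$regions, 3)
  expect_length(enumerate_segments(car8, 8), 1)
  expect_length(enumerate_segments(car8, 10), 1)
  # default stride floor(L/2) double-covers interior regions
  segs2 <- enumerate_segments(forward_car(paste0("b", 1:8)), 6)
  starts <- vapply(segs2, `[[`, integer(1), "start")
  expect_equal(starts, c(1L, 4L, 7L, 10L, 11L))
})

test_that("triangle with unit copy numbers keeps two edges at most", {
  mu <- c(`a@1` = 1L, `b@1` = 1L, `c@1` = 1L)
  edges <- data.frame(key = c("a@1:h--b@1:t", "b@1:h--c@1:t", "a@1:t--c@1:h"),
                      u = c("a@1:h", "b@1:h", "a@1:t"),
                      v = c("b@1:t", "c@1:t", "c@1:h"),
                      weight = c(1, 1, 1))
  sol <- select_adjacencies(edges, mu)
  expect_length(sol$selected, 3)  # distinct marker ends: all three fit
  # same triangle attached to a single marker end per vertex binds at mu
  edges2 <- data.frame(key = c("a@1:h--b@1:h", "b@1:h--c@1:h", "a@1:h--c@1:h"),
                       u = c("a@1:h", "b@1:h", "a@1:h"),
                       v = c("b@1:h", "c@1:h", "c@1:h"),
                       weight = c(1, 1, 1))
  sol2 <- select_adjacencies(edges2, mu)
  expect_length(sol2$selected, 1)
  expect_equal(sol2$weight, oracle_bmatching_weight(edges2, mu))
})

test_that("path graphs with unit copies keep every edge", {
  mu <- stats::setNames(rep(1L, 5), paste0("f", 1:5, "@1"))
  u <- paste0("f", 1:4, "@1:h")
  v <- paste0("f", 2:5, "@1:t")
  edges <- data.frame(key = paste(u, v, sep = "--"), u = u, v = v,
                      weight = c(0.9, 0.5, 0.7, 0.3))
  sol <- select_adjacencies(edges, mu)
  expect_setequal(sol$selected, edges$key)
  expect_equal(sol$weight, sum(edges$weight))
})

test_that("selection equals exhaustive search on random instances", {
  set.seed(11)
  for (rep in 1:60) {
    inst <- random_bmatch_instance(n_loc = sample(3:5, 1),
                                   n_edges = sample(4:10, 1))
    sol <- select_adjacencies(inst$edges, inst$mu)
    expect_equal(sol$weight, oracle_bmatching_weight(inst$edges, inst$mu),
                 tolerance = 1e-9, info = paste("rep", rep))
    # degree feasibility on the marker-end graph (self-loops count twice)
    sel <- inst$edges[inst$edges$key %in% sol$selected, ]
    deg <- table(c(sel$u, sel$v))
    caps <- inst$mu[sub("@1:[ht]$", "@1", names(deg))]
    expect_true(all(as.integer(deg) <= as.integer(caps)))
  }
})

test_that("solutions are canonical under input order and weight scaling", {
  set.seed(12)
  inst <- random_bmatch_instance(n_loc = 4, n_edges = 9)
  sol <- select_adjacencies(inst$edges, inst$mu)
  perm <- sample(nrow(inst$edges))
  sol_perm <- select_adjacencies(inst$edges[perm, ], inst$mu)
  expect_identical(sol$selected, sol_perm$selected)
  scaled <- inst$edges
  scaled$weight <- scaled$weight * 7.3
  sol_scaled <- select_adjacencies(scaled, inst$mu)
  expect_identical(sol$selected, sol_scaled$selected)
  # isolated extra localization changes nothing
  mu2 <- c(inst$mu, `zz@1` = 3L)
  expect_identical(select_adjacencies(inst$edges, mu2)$selected, sol$selected)
})

test_that("induced subgraphs restrict vertices by psi over segment regions", {
  psi <- list(`f1@1` = c("r1", "r2"), `f2@1` = "r2", `f3@1` = "r9")
  inv <- psi_inverse(psi)
  seg <- list(start = 1L, regions = c("r1", "r2"))
  edges <- data.frame(key = c("f1@1:h--f2@1:t", "f2@1:h--f3@1:t"),
                      u = c("f1@1:h", "f2@1:h"),
                      v = c("f2@1:t", "f3@1:t"),
                      weight = c(1, 1))
  gsub <- induced_subgraph(edges, seg, inv, c(`f1@1` = 1L, `f2@1` = 1L, `f3@1` = 1L))
  expect_setequal(gsub$vertices, c("f1@1", "f2@1"))
  expect_identical(gsub$edges$key, "f1@1:h--f2@1:t")
})

test_that("empty graphs and zero-copy vertices yield empty solutions", {
  expect_identical(select_adjacencies(NULL, c(a = 1L))$selected, character(0))
  edges <- data.frame(key = "a@1:h--b@1:t", u = "a@1:h", v = "b@1:t", weight = 1)
  expect_identical(select_adjacencies(edges, c(`a@1` = 0L, `b@1` = 1L))$selected,
                   character(0))
  expect_error(select_adjacencies(transform(edges, weight = -1),
                                  c(`a@1` = 1L, `b@1` = 1L)), "positive")
})
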
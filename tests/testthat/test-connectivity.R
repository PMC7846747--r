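test_that("co-activity matches its closed form on hand cases", {
  ## T_i = 4, T_j = 9, T_ij = 3 -> C = 3 / sqrt(36) = 0.5
  a <- c(rep(1, 4), rep(0, 8))
  b <- c(0, 1, 1, 1, rep(1, 6), 0, 0)
  co <- coactivity_matrix(binary_raster(rbind(a, b)))
  expect_equal(co$T_on, c(a = 4, b = 9))
  expect_equal(co$C[1, 2], 0.5)

  ## identical rows -> C = 1; disjoint rows -> C = 0
  r <- binary_raster(rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1)))
  co <- coactivity_matrix(r)
  expect_equal(co$C[1, 2], 1)
  expect_equal(co$C[1, 3], 0)
})

test_that("co-activity equals a brute-force recount on random rasters", {
  set.seed(99)
  for (rep in 1:40) {
    S <- matrix(rbinom(10 * 150, 1, runif(1, 0.05, 0.6)), 10)
    co <- coactivity_matrix(binary_raster(S))
    expect_identical(unname(co$C[upper.tri(co$C)]),
                     brute_force_coactivity(S)[upper.tri(co$C)])
  }
})

test_that("C is invariant under identical circular shifts of a pair", {
  set.seed(4)
  S <- matrix(rbinom(2 * 300, 1, 0.3), 2)
  base <- coactivity_matrix(binary_raster(S))$C[1, 2]
  for (k in c(7, 100, 299)) {
    Sk <- S[, c((k + 1):300, 1:k), drop = FALSE]
    expect_equal(coactivity_matrix(binary_raster(Sk))$C[1, 2], base)
  }
})

test_that("inactive cells get C = 0, p = 1 and no links", {
  S <- rbind(rep(0L, 100), rep(0L, 100), rbinom(100, 1, 0.5))
  co <- coactivity_matrix(binary_raster(S))
  expect_false(co$active[1])
  expect_equal(co$C[1, 2], 0)
  co <- permutation_significance(co, 200, seed = 1)
  expect_equal(co$p_values[1, 2], 1)
  expect_false(any(co$adjacency[1, ]))
})

test_that("perfectly aligned bursty rows reach the minimum attainable p", {
  ## 10 bursts of 50 frames in 6000 frames, two identical cells; burst
  ## spacing is irregular so no circular shift can re-create the alignment
  s <- rep(0L, 6000)
  starts <- c(1, 451, 1213, 1831, 2563, 3137, 3911, 4397, 5021, 5717)
  for (st in starts) s[st:(st + 49)] <- 1L
  co <- coactivity_matrix(binary_raster(rbind(s, s)))
  co <- permutation_significance(co, n_permutations = 1000, seed = 11)
  expect_equal(co$p_values[1, 2], 1 / 1001)
  expect_true(co$adjacency[1, 2])
})

test_that("permutation significance is deterministic given its seed", {
  set.seed(2)
  S <- matrix(rbinom(8 * 500, 1, 0.2), 8)
  co <- coactivity_matrix(binary_raster(S))
  p1 <- permutation_significance(co, 300, seed = 5)$p_values
  p2 <- permutation_significance(co, 300, seed = 5)$p_values
  expect_identical(p1, p2)
})

test_that("growing alpha never removes links; growing the hub threshold never adds hubs", {
  set.seed(3)
  d <- generate_islet_traces(islet_sim_config(n_cells = 20, duration_s = 120,
      protocol = stim_protocol("glucose", 0, 120, 0.8), seed = 3))
  co <- coactivity_matrix(d$truth_raster)
  co1 <- permutation_significance(co, 300, alpha = 0.01, seed = 9)
  co2 <- permutation_significance(co, 300, alpha = 0.10, seed = 9)
  expect_true(all(co2$adjacency[co1$adjacency]))
  h60 <- classify_hubs(co2, threshold_percent = 60)
  h80 <- classify_hubs(co2, threshold_percent = 80)
  expect_true(all(h60$is_hub[h80$is_hub]))
})

test_that("hub classification follows the link-percentage rule", {
  ## per-cell link counts [9, 9, 1, 1, 1, 0] (the count sequence is not a
  ## symmetric graph, so rows are planted directly; classification uses
  ## per-cell counts only)
  A <- matrix(FALSE, 6, 10)
  A[1, c(2:10)] <- TRUE
  A[2, c(1, 3:10)] <- TRUE
  A[3, 1] <- A[4, 1] <- A[5, 2] <- TRUE
  co <- structure(list(C = matrix(0.5, 6, 10), adjacency = A,
                       active = rep(TRUE, 6),
                       cell_ids = letters[1:6], T_on = rep(10, 6)),
                  class = "coactivity")
  h <- classify_hubs(co)
  expect_equal(h$link_count, c(9, 9, 1, 1, 1, 0))
  expect_equal(h$link_percent, c(100, 100, 100 / 9, 100 / 9, 100 / 9, 0))
  expect_equal(which(h$is_hub), 1:2)
  expect_equal(attr(h, "hub_fraction"), 2 / 6)
})

test_that("hub classification handles empty and saturated graphs", {
  S <- matrix(rbinom(6 * 200, 1, 0.3), 6)
  co <- coactivity_matrix(binary_raster(S))
  co$adjacency <- matrix(FALSE, 6, 6)
  expect_equal(sum(classify_hubs(co)$is_hub), 0)
  co$adjacency <- !diag(TRUE, 6)
  h <- classify_hubs(co)
  expect_true(all(h$is_hub))
  expect_true(all(h$link_percent == 100))
})

test_that("n_minus_1 normalization is available as the alternative reading", {
  S <- matrix(rbinom(5 * 200, 1, 0.4), 5)
  co <- coactivity_matrix(binary_raster(S))
  co$adjacency <- matrix(FALSE, 5, 5)
  co$adjacency[1, 2:5] <- co$adjacency[2:5, 1] <- TRUE
  h <- classify_hubs(co, normalization = "n_minus_1")
  expect_equal(h$link_percent[1], 100)
  expect_equal(h$link_percent[2], 25)
})

test_that("connectivity summary counts significant pairs among active cells", {
  S <- matrix(rbinom(5 * 200, 1, 0.4), 5)
  co <- coactivity_matrix(binary_raster(S))
  A <- matrix(FALSE, 5, 5)
  A[1, 2] <- A[2, 1] <- A[1, 3] <- A[3, 1] <- A[4, 5] <- A[5, 4] <- TRUE
  co$adjacency <- A
  cs <- connectivity_summary(co)
  expect_equal(cs$percent_connected_pairs, 30)    # 3 of C(5,2) = 10
  co$adjacency <- matrix(FALSE, 5, 5)
  expect_equal(connectivity_summary(co)$percent_connected_pairs, 0)
  co$adjacency <- !diag(TRUE, 5)
  expect_equal(connectivity_summary(co)$percent_connected_pairs, 100)
})

test_that("connectivity maps carry coordinates, hubs and edges faithfully", {
  d <- generate_islet_traces(islet_sim_config(n_cells = 15, duration_s = 60,
      protocol = stim_protocol("glucose", 0, 60, 0.8), seed = 6))
  co <- coactivity_matrix(d$truth_raster)
  co <- permutation_significance(co, 200, seed = 2)
  h <- classify_hubs(co)
  map <- build_connectivity_map(co, h, d$traces$coords)
  expect_equal(nrow(map$nodes), 15)
  expect_identical(map$nodes$is_hub, h$is_hub)
  expect_identical(map$nodes$x, d$traces$coords$x)
  if (nrow(map$edges)) {
    expect_true(all(map$edges$cell_a %in% map$nodes$cell_id))
    expect_true(all(map$edges$cell_b %in% map$nodes$cell_id))
    expect_true(all(map$edges$p <= co$alpha))
  }
  expect_error(build_connectivity_map(co, h, NULL), "oordinates")
  bad <- d$traces$coords; bad$x[3] <- NA
  expect_error(build_connectivity_map(co, h, bad), "cell_003")
})
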
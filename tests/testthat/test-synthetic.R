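test_that("stimulation protocols validate their structure", {
  p <- stim_protocol(c("baseline", "glucose"), c(0, 60), c(60, 180), c(0.1, 0.8))
  expect_s3_class(p, "stim_protocol")
  expect_error(stim_protocol("espresso", 0, 60, 0.5), "unknown label")
  expect_error(stim_protocol(c("baseline", "glucose"), c(0, 50), c(60, 180),
                             c(0.1, 0.8)), "non-overlapping")
  expect_error(stim_protocol("glucose", 60, 60, 0.5), "start_s")
  expect_error(stim_protocol("glucose", 0, 60, 1.5), "\\[0, 1\\]")
})

test_that("islet simulation is deterministic given the seed", {
  cfg <- islet_sim_config(n_cells = 15, duration_s = 30, seed = 7)
  d1 <- generate_islet_traces(cfg)
  d2 <- generate_islet_traces(cfg)
  expect_identical(d1$traces$values, d2$traces$values)
  expect_identical(d1$truth_raster$states, d2$truth_raster$states)
  expect_identical(d1$truth_hubs, d2$truth_hubs)
  d3 <- generate_islet_traces(islet_sim_config(n_cells = 15, duration_s = 30,
                                               seed = 8))
  expect_false(identical(d1$traces$values, d3$traces$values))
})

test_that("simulated datasets respect their declared structure", {
  cfg <- islet_sim_config(n_cells = 24, hub_fraction = 0.125, duration_s = 30,
                          seed = 3)
  d <- generate_islet_traces(cfg)
  expect_equal(sum(d$truth_hubs), round(0.125 * 24))
  expect_equal(dim(d$traces$values), dim(d$truth_raster$states))
  expect_true(all(d$truth_raster$states %in% c(0L, 1L)))
  expect_equal(nrow(d$traces$coords), 24)
  expect_true(all(is.finite(d$traces$values)))
})

test_that("invalid simulator configuration names the offending field", {
  expect_error(islet_sim_config(n_cells = -3), "n_cells")
  expect_error(islet_sim_config(hub_fraction = 1.2), "hub_fraction")
  expect_error(islet_sim_config(noise_sd = NaN), "noise_sd")
  expect_error(islet_sim_config(duration_s = 0.01), "duration_s|at least 2")
})

test_that("truth ON fraction rises monotonically with drive level", {
  drives <- c(0.1, 0.4, 0.8)
  on_frac <- sapply(1:4, function(seed) {
    proto <- stim_protocol(rep("glucose", 3), c(0, 100, 200), c(100, 200, 300),
                           drives)
    d <- generate_islet_traces(islet_sim_config(
      n_cells = 30, duration_s = 300, protocol = proto, seed = seed))
    tt <- trace_times(d$traces)
    sapply(seq_along(drives), function(k) {
      mean(d$truth_raster$states[, tt >= (k - 1) * 100 & tt < k * 100])
    })
  })
  avg <- rowMeans(on_frac)
  expect_true(all(diff(avg) > 0))
})

test_that("KCl depolarisation forces all cells ON; silencing suppresses onsets", {
  proto <- stim_protocol(c("glucose", "kcl", "silenced"),
                         c(0, 60, 90), c(60, 90, 150), c(0.8, 1, 0.05))
  d <- generate_islet_traces(islet_sim_config(n_cells = 20, duration_s = 150,
                                              protocol = proto, seed = 2))
  tt <- trace_times(d$traces)
  expect_true(all(d$truth_raster$states[, tt >= 60 & tt < 90] == 1L))
  glu_on <- mean(d$truth_raster$states[, tt < 60])
  sil <- d$truth_raster$states[, tt >= 95]   # allow bursts started at KCl to end
  expect_lt(mean(sil), glu_on / 2)
})

test_that("stain image generation is deterministic and carries ground truth", {
  cfg <- stain_sim_config(n_cells = 12, seed = 5)
  g1 <- generate_stain_image(cfg)
  g2 <- generate_stain_image(cfg)
  expect_identical(g1$image, g2$image)
  expect_equal(nrow(g1$cells), 12)
  expect_true(all(g1$cells$class %in% c("LOW", "HIGH")))
  ## pairwise separation respects the well-separated regime
  D <- as.matrix(dist(g1$cells[, c("x", "y")]))
  expect_gte(min(D[upper.tri(D)]), 4 * cfg$nucleus_sigma_px)
})

test_that("stain generator rejects impossible configurations", {
  expect_error(stain_sim_config(low_mean = 10, high_mean = 5), "low_mean")
  expect_error(generate_stain_image(
    stain_sim_config(n_cells = 500, image_shape = c(64, 64), seed = 1)),
    "cannot place")
})
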
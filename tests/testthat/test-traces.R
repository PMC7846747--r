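test_that("F/F_min normalization follows the minimum-fluorescence convention", {
  ## constant trace: self-ratio is 1 everywhere
  tr <- fluorescence_traces(matrix(3, 2, 200), frame_rate_hz = 20)
  expect_true(all(normalize_traces(tr, "f_over_fmin")$values == 1))

  ## baseline 1.0 then plateau 2.4, F_min from the baseline epoch
  ep <- stim_protocol(c("baseline", "glucose"), c(0, 5), c(5, 10), c(0.1, 0.8))
  x <- c(rep(1, 100), rep(2.4, 100))
  tr <- fluorescence_traces(matrix(x, 1), frame_rate_hz = 20, epochs = ep)
  nrm <- normalize_traces(tr, "f_over_fmin")
  expect_equal(unname(nrm$f_min), 1)
  expect_equal(unname(nrm$values[1, 150]), 2.4)
})

test_that("ratiometric modes return the elementwise channel quotient", {
  ch1 <- fluorescence_traces(matrix(2, 1, 50), frame_rate_hz = 10)
  ch2 <- matrix(1, 1, 50)
  expect_true(all(normalize_traces(ch1, "fura_340_385", ch2)$values == 2))
  expect_error(normalize_traces(ch1, "fura_340_385"), "channel2")
  ch2[25] <- 0
  expect_error(normalize_traces(ch1, "fura_340_385", ch2), "zero denominator")
})

test_that("normalization refuses non-positive F_min", {
  tr <- fluorescence_traces(matrix(c(rep(0, 50), rep(1, 50)), 1),
                            frame_rate_hz = 20)
  expect_error(normalize_traces(tr, "f_over_fmin"), "F_min")
})

test_that("binarization reproduces duty cycles exactly on noiseless waves", {
  ## 30% duty square wave at the standard 20% threshold
  x <- square_wave(6000, 0.3)
  r <- binarize_activity(as_norm_traces(x), threshold_fraction = 0.20)
  expect_equal(mean(r$states), 0.30)
  ## exactness holds for any threshold strictly between trough and crest
  for (thr in c(0.05, 0.5, 0.95)) {
    r <- binarize_activity(as_norm_traces(x), threshold_fraction = thr)
    expect_equal(mean(r$states), 0.30)
  }
})

test_that("binarization limiting and degenerate cases", {
  expect_true(all(binarize_activity(as_norm_traces(rep(2, 100)))$states == 0))
  x <- square_wave(1000, 0.3)
  r0 <- binarize_activity(as_norm_traces(x), threshold_fraction = 0)
  expect_equal(r0$states[1, ], as.integer(x > min(x)))
})

test_that("binarized rasters track the simulator ground truth", {
  agree <- sapply(1:4, function(seed) {
    d <- generate_islet_traces(reference_islet_config(seed))
    den <- detrend_denoise(normalize_traces(d$traces))
    r <- binarize_activity(den)
    mean(r$states == d$truth_raster$states)
  })
  expect_gte(mean(agree), 0.9)
})

test_that("response metrics match hand-computed examples", {
  ep <- stim_protocol(c("baseline", "glucose"), c(0, 30), c(30, 90),
                      c(0.1, 0.8))
  fr <- 20
  x <- c(rep(1, 30 * fr), rep(2, 60 * fr))
  tr <- as_norm_traces(x, frame_rate_hz = fr, epochs = ep)
  ## raster with three 2-s ON runs inside the 60-s stimulus
  s <- rep(0L, 90 * fr)
  for (st in c(35, 55, 75)) s[(st * fr):(st * fr + 2 * fr - 1)] <- 1L
  rm <- response_metrics(tr, binary_raster(matrix(s, 1)), epochs = ep)
  expect_equal(rm$amplitude, 1.0)
  expect_equal(rm$pulse_duration_s, 2.0)
  expect_equal(rm$oscillation_frequency_hz, 3 / 60)
  expect_true(rm$responsive)
})

test_that("noise-only stimulation is declared non-responsive", {
  ep <- stim_protocol(c("baseline", "glucose"), c(0, 30), c(30, 90),
                      c(0.1, 0.8))
  prop <- sapply(1:5, function(seed) {
    set.seed(seed)
    V <- matrix(1 + rnorm(20 * 1800, sd = 0.05), 20)
    tr <- as_norm_traces(V, epochs = ep)
    r <- binarize_activity(tr)
    mean(response_metrics(tr, r, epochs = ep)$responsive)
  })
  expect_lte(mean(prop), 0.05)
})

test_that("response metrics demand the named epochs", {
  ep <- stim_protocol("glucose", 0, 60, 0.8)
  tr <- as_norm_traces(matrix(1, 1, 1200), epochs = ep)
  expect_error(response_metrics(tr, binary_raster(matrix(0L, 1, 1200)),
                                epochs = ep), "baseline")
})
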
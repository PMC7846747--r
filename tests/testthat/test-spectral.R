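test_that("the wavelet transform is linear in the zero and scaling senses", {
  expect_true(all(morlet_cwt(rep(0, 1000), 20)$power == 0))
  ## doubling amplitude quadruples total power (within 1%)
  t <- seq(0.05, 120, by = 0.05)
  x <- sin(2 * pi * t / 7)
  p1 <- sum(morlet_cwt(x, 20)$power)
  p2 <- sum(morlet_cwt(2 * x, 20)$power)
  expect_equal(p2 / p1, 4, tolerance = 0.01)
})

test_that("a 10-s sinusoid peaks at a 10-s period within one scale step", {
  t <- seq(0.05, 300, by = 0.05)
  sp <- morlet_cwt(sin(2 * pi * t / 10), 20)
  peak <- sp$periods_s[which.max(rowMeans(sp$power))]
  step <- 2^sp$dj
  expect_gte(peak, 10 / step)
  expect_lte(peak, 10 * step)
})

test_that("bias correction equalizes peak power across periods", {
  t <- seq(0.05, 300, by = 0.05)
  sp5 <- morlet_cwt(sin(2 * pi * t / 5), 20)
  sp20 <- morlet_cwt(sin(2 * pi * t / 20), 20)
  corrected <- max(rowMeans(sp5$power)) / max(rowMeans(sp20$power))
  expect_gt(corrected, 1 / 1.1)
  expect_lt(corrected, 1.1)
  ## without the 1/scale correction the long period dominates severalfold
  raw <- max(rowMeans(sp20$power_uncorrected)) /
    max(rowMeans(sp5$power_uncorrected))
  expect_gt(raw, 2)
})

test_that("frequency axis agrees with an independent FFT periodogram", {
  fr <- 20
  for (period in c(4, 12)) {
    t <- seq(1 / fr, 240, by = 1 / fr)
    x <- sin(2 * pi * t / period)
    ## periodogram peak as the independent oracle
    pg <- Mod(fft(x))^2
    freqs <- (seq_along(x) - 1) * fr / length(x)
    half <- 2:(length(x) / 2)
    f_star <- freqs[half][which.max(pg[half])]
    sp <- morlet_cwt(x, fr)
    peak <- sp$periods_s[which.max(rowMeans(sp$power))]
    expect_equal(peak, 1 / f_star, tolerance = 2^sp$dj - 1 + 0.02)
  }
})

test_that("dominant period tracks a mid-record period switch", {
  fr <- 20
  t1 <- seq(1 / fr, 150, by = 1 / fr)
  t2 <- seq(1 / fr, 150, by = 1 / fr)
  x <- c(sin(2 * pi * t1 / 20), sin(2 * pi * t2 / 5))
  sp <- morlet_cwt(x, fr)
  early <- dominant_period(sp, window = c(40, 110))
  late <- dominant_period(sp, window = c(190, 260))
  two_steps <- 2^(2 * sp$dj)
  expect_lte(abs(log(early$median_period_s / 20)), log(two_steps))
  expect_lte(abs(log(late$median_period_s / 5)), log(two_steps))
})

test_that("a stationary sinusoid has a constant dominant period", {
  t <- seq(0.05, 200, by = 0.05)
  sp <- morlet_cwt(sin(2 * pi * t / 8), 20)
  dp <- dominant_period(sp, window = c(40, 160))
  vals <- unique(dp$period_s[!is.na(dp$period_s)])
  expect_lte(length(vals), 2)          # at most neighbouring scale steps
  expect_equal(dp$median_period_s, 8, tolerance = 2^sp$dj - 1 + 0.02)
})

test_that("wavelet input contracts are enforced", {
  expect_error(morlet_cwt(1:10, 20), "32")
  sp <- morlet_cwt(sin(seq(0, 50, by = 0.05)), 20)
  expect_error(dominant_period(sp, window = c(1e5, 2e5)), "outside")
})

test_that("averaging spectra preserves the axes and the mean", {
  t <- seq(0.05, 100, by = 0.05)
  s1 <- morlet_cwt(sin(2 * pi * t / 6), 20)
  s2 <- morlet_cwt(sin(2 * pi * t / 6 + 1), 20)
  m <- mean_wavelet_spectrum(list(s1, s2))
  expect_equal(m$power, (s1$power + s2$power) / 2)
  expect_identical(m$periods_s, s1$periods_s)
})
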
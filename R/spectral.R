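#' Bias-corrected continuous Morlet wavelet spectrum
#'
#' Computes the continuous wavelet transform of a single detrended trace
#' with the Morlet mother wavelet (\eqn{\omega_0 = 6}) over dyadic scales
#' \eqn{s_j = s_0 2^{j \cdot dj}} with \eqn{s_0 = 2\,dt}, up to half the
#' record length, using FFT convolution with zero-padding to the next power
#' of two. Power is reported bias-corrected as \eqn{|W|^2 / s}: dividing by
#' scale prevents the compression of power as period lengthens, so
#' oscillations of equal amplitude show equal peak power whatever their
#' period. The cone of influence (COI) marks, per time point, the longest
#' period free of edge effects (the wavelet e-folding time
#' \eqn{\sqrt{2}\,s}).
#'
#' @param x numeric trace (detrended), length >= 32.
#' @param frame_rate_hz sampling rate in Hz.
#' @param dj scale resolution in octaves (default 1/12, i.e. 12 sub-octaves).
#' @param omega0 Morlet nondimensional frequency (default 6).
#' @return An object of class `wavelet_spectrum`: `power` (period x time
#'   matrix, bias-corrected), `power_uncorrected` (\eqn{|W|^2}),
#'   `periods_s`, `times_s`, `coi_s` (max reliable period per time point),
#'   `scales`, `dj`, `omega0`.
#' @examples
#' x <- sin(2 * pi * seq(0, 120, by = 0.05) / 10)
#' sp <- morlet_cwt(x, frame_rate_hz = 20)
#' sp$periods_s[which.max(rowMeans(sp$power))]  # ~10 s
#' @export
morlet_cwt <- function(x, frame_rate_hz, dj = 1 / 12, omega0 = 6) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 32) stop("morlet_cwt requires at least 32 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("morlet_cwt requires finite input", call. = FALSE)
  dt <- 1 / frame_rate_hz

  n_pad <- next_pow2(n)
  xp <- c(x - mean(x), rep(0, n_pad - n))
  xh <- stats::fft(xp)

  ## angular frequencies of the padded FFT grid
  k <- c(seq(0, n_pad / 2), seq(-n_pad / 2 + 1, -1)) * (2 * pi) / (n_pad * dt)

  s0 <- 2 * dt
  J <- floor(log2(n * dt / s0) / dj)
  scales <- s0 * 2^(seq(0, J) * dj)
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  periods <- fourier_factor * scales

  W <- matrix(0 + 0i, length(scales), n)
  norm_base <- sqrt(2 * pi / dt) * pi^(-1 / 4)
  pos <- k > 0
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi_hat <- numeric(n_pad)
    psi_hat[pos] <- norm_base * sqrt(s) * exp(-(s * k[pos] - omega0)^2 / 2)
    Wj <- stats::fft(xh * psi_hat, inverse = TRUE) / n_pad
    W[j, ] <- Wj[seq_len(n)]
  }
  power_raw <- Mod(W)^2
  power <- power_raw / scales              # bias correction: |W|^2 / scale

  times <- (seq_len(n) - 1) * dt
  edge <- pmin(times, rev(times))
  coi <- fourier_factor / sqrt(2) * pmax(edge, dt * 1e-5)

  structure(list(power = power, power_uncorrected = power_raw,
                 periods_s = periods, times_s = times, coi_s = coi,
                 scales = scales, dj = dj, omega0 = omega0),
            class = "wavelet_spectrum")
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf("wavelet_spectrum: %d periods (%.2f-%.1f s) x %d time points\n",
              length(x$periods_s), min(x$periods_s), max(x$periods_s),
              length(x$times_s)))
  invisible(x)
}

#' Time-localized dominant oscillation period
#'
#' At each time point inside the window, the dominant period is the argmax
#' of bias-corrected power over periods shorter than the local cone of
#' influence; the window summary is the median of those values.
#'
#' @param spectrum a [morlet_cwt()] result.
#' @param window numeric `c(start_s, end_s)`; defaults to the full record.
#' @return A list of class `dominant_period`: `times_s`, `period_s`
#'   (per time point, NA where no period lies inside the COI), and
#'   `median_period_s`.
#' @export
dominant_period <- function(spectrum, window = NULL) {
  stopifnot(inherits(spectrum, "wavelet_spectrum"))
  tt <- spectrum$times_s
  window <- window %||% range(tt)
  sel <- which(tt >= window[1] & tt <= window[2])
  if (!length(sel)) stop("window lies outside the record", call. = FALSE)
  per <- rep(NA_real_, length(sel))
  for (j in seq_along(sel)) {
    i <- sel[j]
    ok <- spectrum$periods_s <= spectrum$coi_s[i]
    if (!any(ok)) next
    p <- spectrum$power[ok, i]
    per[j] <- spectrum$periods_s[ok][which.max(p)]
  }
  if (all(is.na(per))) {
    stop("window lies entirely outside the cone of influence", call. = FALSE)
  }
  structure(list(times_s = tt[sel], period_s = per,
                 median_period_s = stats::median(per, na.rm = TRUE)),
            class = "dominant_period")
}

#' @export
print.dominant_period <- function(x, ...) {
  cat(sprintf("dominant_period: median %.2f s over %d time points\n",
              x$median_period_s, sum(!is.na(x$period_s))))
  invisible(x)
}

#' Average wavelet spectra across cells
#'
#' Arithmetic mean of bias-corrected power matrices computed on the same
#' frame grid (the "mean wave" convention for summarising a population of
#' traces).
#'
#' @param spectra list of [morlet_cwt()] results with identical axes.
#' @return A `wavelet_spectrum` holding the mean power.
#' @export
mean_wavelet_spectrum <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  ref <- spectra[[1]]
  for (s in spectra[-1]) {
    if (!isTRUE(all.equal(s$periods_s, ref$periods_s)) ||
        length(s$times_s) != length(ref$times_s)) {
      stop("spectra must share period and time axes", call. = FALSE)
    }
  }
  ref$power <- Reduce(`+`, lapply(spectra, `[[`, "power")) / length(spectra)
  ref$power_uncorrected <-
    Reduce(`+`, lapply(spectra, `[[`, "power_uncorrected")) / length(spectra)
  ref
}

#' Plot a wavelet power spectrum
#'
#' Period-versus-time heatmap of bias-corrected power with the cone of
#' influence overlaid; the region above the COI line is edge-affected.
#'
#' @param x a `wavelet_spectrum`.
#' @param ... passed to [graphics::image()].
#' @export
plot.wavelet_spectrum <- function(x, ...) {
  graphics::image(x$times_s, log2(x$periods_s), t(x$power),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "time (s)", ylab = "period (s, log2)",
                  yaxt = "n", useRaster = TRUE, ...)
  at <- pretty(log2(x$periods_s))
  graphics::axis(2, at = at, labels = signif(2^at, 3))
  graphics::lines(x$times_s, log2(x$coi_s), col = "white", lty = 2)
  invisible(x)
}
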
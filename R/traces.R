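#' Normalize fluorescence traces
#'
#' Converts raw fluorescence to the dimensionless conventions of Ca2+ and
#' cAMP imaging: `"f_over_fmin"` divides each cell's trace by its minimum
#' fluorescence F_min, estimated as the 5th percentile of the baseline epoch
#' (or of the whole trace when no baseline epoch is present) so single-frame
#' dropouts do not set the denominator; `"fura_340_385"` and
#' `"epac_cer_cit"` return the elementwise ratio of the two excitation /
#' emission channels (340/385 nm for Fura2, Cerulean/Citrine for Epac);
#' `"raw"` passes values through unchanged.
#'
#' @param raw a [fluorescence_traces()] object (the numerator channel for
#'   ratio modes).
#' @param mode one of `"f_over_fmin"`, `"fura_340_385"`, `"epac_cer_cit"`,
#'   `"raw"`.
#' @param channel2 for ratio modes, a matrix or `fluorescence_traces` with
#'   the denominator channel (385 nm or Citrine), same dimensions as `raw`.
#' @param fmin_quantile quantile used for the F_min estimate.
#' @return An object of class `normalized_traces`: list with `values`,
#'   `frame_rate_hz`, `cell_ids`, `coords`, `epochs`, `mode`, and `f_min`
#'   (per-cell, `"f_over_fmin"` mode only).
#' @examples
#' tr <- fluorescence_traces(matrix(2, 1, 100), frame_rate_hz = 20)
#' range(normalize_traces(tr, "f_over_fmin")$values)  # all 1
#' @export
normalize_traces <- function(raw, mode = c("f_over_fmin", "fura_340_385",
                                           "epac_cer_cit", "raw"),
                             channel2 = NULL, fmin_quantile = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(raw, "fluorescence_traces"))
  V <- raw$values
  f_min <- NULL
  if (mode == "f_over_fmin") {
    base_idx <- seq_len(ncol(V))
    if (!is.null(raw$epochs) && "baseline" %in% raw$epochs$label) {
      bi <- epoch_frames(raw$epochs, "baseline", trace_times(raw))
      if (length(bi) >= 2) base_idx <- bi
    }
    f_min <- apply(V[, base_idx, drop = FALSE], 1, stats::quantile,
                   probs = fmin_quantile, names = FALSE)
    bad <- which(f_min <= 0)
    if (length(bad)) {
      stop(sprintf("non-positive F_min for cells: %s",
                   paste(raw$cell_ids[bad], collapse = ", ")), call. = FALSE)
    }
    out <- V / f_min
  } else if (mode %in% c("fura_340_385", "epac_cer_cit")) {
    if (is.null(channel2)) stop("ratio modes require channel2", call. = FALSE)
    V2 <- if (inherits(channel2, "fluorescence_traces")) channel2$values else
      as.matrix(channel2)
    if (!all(dim(V2) == dim(V))) stop("channel matrices must share dimensions",
                                      call. = FALSE)
    bad <- which(apply(V2, 1, function(r) any(r == 0)))
    if (length(bad)) {
      stop(sprintf("zero denominator frames for cells: %s",
                   paste(raw$cell_ids[bad], collapse = ", ")), call. = FALSE)
    }
    out <- V / V2
  } else {
    out <- V
  }
  structure(list(values = out, frame_rate_hz = raw$frame_rate_hz,
                 cell_ids = raw$cell_ids, coords = raw$coords,
                 epochs = raw$epochs, mode = mode, f_min = f_min),
            class = "normalized_traces")
}

#' @export
print.normalized_traces <- function(x, ...) {
  cat(sprintf("normalized_traces (%s): %d cells x %d frames @ %g Hz\n",
              x$mode, nrow(x$values), ncol(x$values), x$frame_rate_hz))
  invisible(x)
}

#' Remove noise and baseline trends via EMD
#'
#' Per cell, runs [emd_decompose()] and reconstructs the signal from the
#' intermediate modes only. Noise components are the leading IMFs whose mean
#' period (from their zero-crossing rate) is shorter than `noise_period_s`
#' — Ca2+ bursts last at least a few hundred milliseconds, so anything
#' faster is measurement noise. On a noiseless signal no IMF is that fast
#' and nothing is dropped.
#' Trend components are the residue plus any IMF whose mean period exceeds
#' `trend_period_fraction` of the recording length. Cells that yield fewer
#' than two IMFs pass through with only the residue removed.
#'
#' @param traces a `normalized_traces` (or `fluorescence_traces`) object.
#' @param noise_period_s IMFs faster than this mean period (seconds) are
#'   treated as noise.
#' @param min_drop_imfs minimum number of leading IMFs dropped as noise
#'   (set to 1 to always discard the first IMF).
#' @param trend_period_fraction IMFs with mean period longer than this
#'   fraction of the record are treated as trend.
#' @param ... passed to [emd_decompose()].
#' @return A `normalized_traces` object of the same shape, with an added
#'   `denoise_log` data.frame (per-cell IMF counts and dropped components).
#' @export
detrend_denoise <- function(traces, noise_period_s = 0.5, min_drop_imfs = 0,
                            trend_period_fraction = 0.5, ...) {
  V <- traces$values
  n_frames <- ncol(V)
  min_period_frames <- noise_period_s * traces$frame_rate_hz
  out <- V
  log_rows <- vector("list", nrow(V))
  for (i in seq_len(nrow(V))) {
    dec <- emd_decompose(V[i, ], ...)
    k <- ncol(dec$imfs)
    if (k < 2) {
      out[i, ] <- V[i, ] - dec$residue
      log_rows[[i]] <- data.frame(cell = i, n_imfs = k, kept = k,
                                  note = "fewer than 2 IMFs; residue removed only")
      next
    }
    periods <- apply(dec$imfs, 2, mean_period_frames)
    ## noise = leading run of fast IMFs (never the slow tail)
    fast <- periods < min_period_frames
    n_noise <- if (all(fast)) k else which(!fast)[1] - 1L
    n_noise <- max(n_noise, min_drop_imfs)
    keep <- seq_len(k) > n_noise &
      periods <= trend_period_fraction * n_frames
    out[i, ] <- if (any(keep)) rowSums(dec$imfs[, keep, drop = FALSE]) else 0
    log_rows[[i]] <- data.frame(cell = i, n_imfs = k, kept = sum(keep),
                                note = "")
  }
  res <- traces
  res$values <- out
  res$denoise_log <- do.call(rbind, log_rows)
  res
}

#' Construct a binary activity raster
#'
#' @param states cell x frame matrix whose entries are exactly 0 or 1.
#' @param threshold_fraction the binarization threshold that produced it
#'   (NA for ground-truth rasters).
#' @return An object of class `binary_raster`.
#' @export
binary_raster <- function(states, threshold_fraction = NA_real_) {
  states <- as.matrix(states)
  if (!all(states %in% c(0, 1))) stop("raster entries must be 0 or 1",
                                      call. = FALSE)
  storage.mode(states) <- "integer"
  structure(list(states = states, threshold_fraction = threshold_fraction),
            class = "binary_raster")
}

#' @export
print.binary_raster <- function(x, ...) {
  cat(sprintf("binary_raster: %d cells x %d frames, ON fraction %.3f\n",
              nrow(x$states), ncol(x$states), mean(x$states)))
  invisible(x)
}

#' Plot a binary raster
#'
#' Standard raster plot: one row per cell, filled where the cell is ON.
#' @param x a `binary_raster`.
#' @param frame_rate_hz optional frame rate to label the x axis in seconds.
#' @param ... passed to [graphics::image()].
#' @export
plot.binary_raster <- function(x, frame_rate_hz = NULL, ...) {
  tt <- seq_len(ncol(x$states))
  xlab <- "frame"
  if (!is.null(frame_rate_hz)) {
    tt <- (tt - 1) / frame_rate_hz
    xlab <- "time (s)"
  }
  graphics::image(tt, seq_len(nrow(x$states)), t(x$states),
                  col = c("white", "black"), xlab = xlab, ylab = "cell",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Binarize activity with a fractional threshold
#'
#' A cell is ON wherever its (denoised) signal exceeds its robust minimum by
#' more than `threshold_fraction` of its robust dynamic range; the default
#' 20% threshold is the convention for binarizing islet Ca2+ activity. The
#' robust extrema are the 1st and 99th percentiles of the cell's trace, so a
#' few residual spikes do not stretch the range. Cells with zero dynamic
#' range are returned all-OFF.
#'
#' @param traces a `normalized_traces` object (typically denoised).
#' @param threshold_fraction fraction of the dynamic range, default 0.20.
#' @param robust_quantiles the two probabilities defining the robust extrema.
#' @return A [binary_raster()] with the source threshold recorded.
#' @examples
#' sq <- matrix(rep(c(1, 1, 1, 2, 2, 1, 1, 1, 1, 1), 10), 1, 100)
#' tr <- structure(list(values = sq, frame_rate_hz = 20,
#'                      cell_ids = "c1", coords = NULL, epochs = NULL),
#'                 class = "normalized_traces")
#' mean(binarize_activity(tr)$states)  # duty cycle 0.2
#' @export
binarize_activity <- function(traces, threshold_fraction = 0.20,
                              robust_quantiles = c(0.01, 0.99)) {
  check_scalar(threshold_fraction, "threshold_fraction", lower = 0, upper = 1)
  V <- traces$values
  states <- matrix(0L, nrow(V), ncol(V))
  for (i in seq_len(nrow(V))) {
    q <- stats::quantile(V[i, ], probs = robust_quantiles, names = FALSE)
    rng <- q[2] - q[1]
    if (rng <= 0) next                      # degenerate cell stays all-OFF
    states[i, ] <- as.integer(V[i, ] - q[1] > threshold_fraction * rng)
  }
  rownames(states) <- traces$cell_ids
  r <- binary_raster(states, threshold_fraction)
  r$source_mode <- traces$mode %||% NA_character_
  r
}

#' Per-cell stimulus response metrics
#'
#' Summarises each cell's response to a stimulation epoch relative to
#' baseline: `amplitude` is the difference of the mean normalized signal
#' (stimulus minus baseline); `pulse_duration_s` the mean length of
#' contiguous ON runs of the binary raster during the stimulus;
#' `responsive` flags cells whose amplitude exceeds `k_sd` baseline standard
#' deviations; `oscillation_frequency_hz` counts ON-run onsets per second of
#' stimulus.
#'
#' @param traces a `normalized_traces` object.
#' @param raster the matching [binary_raster()].
#' @param epochs a [stim_protocol()]; defaults to the one carried by
#'   `traces`. Must contain a `baseline` and at least one stimulus epoch.
#' @param stimulus_label epoch label(s) treated as the stimulus.
#' @param k_sd responsiveness criterion, in baseline standard deviations.
#' @return A data.frame of class `response_metrics` with one row per cell.
#' @export
response_metrics <- function(traces, raster, epochs = traces$epochs,
                             stimulus_label = "glucose", k_sd = 2) {
  if (is.null(epochs)) stop("response_metrics requires epochs", call. = FALSE)
  tt <- trace_times(traces)
  base_idx <- epoch_frames(epochs, "baseline", tt)
  stim_idx <- epoch_frames(epochs, stimulus_label, tt)
  if (length(base_idx) < 2) stop("no baseline epoch in protocol", call. = FALSE)
  if (length(stim_idx) < 2) {
    stop(sprintf("no '%s' epoch in protocol", paste(stimulus_label, collapse = "/")),
         call. = FALSE)
  }
  V <- traces$values
  S <- raster$states
  stim_dur <- length(stim_idx) / traces$frame_rate_hz
  n <- nrow(V)
  amplitude <- numeric(n); pulse <- numeric(n); freq <- numeric(n)
  responsive <- logical(n)
  for (i in seq_len(n)) {
    b <- V[i, base_idx]; s <- V[i, stim_idx]
    amplitude[i] <- mean(s) - mean(b)
    responsive[i] <- amplitude[i] > k_sd * stats::sd(b)
    runs <- on_runs(S[i, stim_idx])
    pulse[i] <- if (length(runs$length)) {
      mean(runs$length) / traces$frame_rate_hz
    } else 0
    freq[i] <- length(runs$length) / stim_dur
  }
  out <- data.frame(cell_id = traces$cell_ids, amplitude = amplitude,
                    pulse_duration_s = pulse, responsive = responsive,
                    oscillation_frequency_hz = freq,
                    stringsAsFactors = FALSE)
  class(out) <- c("response_metrics", "data.frame")
  out
}
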
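# Shared fixtures, built in code.

## Wrap a plain matrix as a normalized trace set.
as_norm_traces <- function(m, frame_rate_hz = 20, epochs = NULL, mode = "raw") {
  m <- if (is.matrix(m)) m else matrix(m, nrow = 1)
  structure(list(values = m, frame_rate_hz = frame_rate_hz,
                 cell_ids = sprintf("cell_%03d", seq_len(nrow(m))),
                 coords = NULL, epochs = epochs, mode = mode),
            class = "normalized_traces")
}

## Noiseless square wave of given duty cycle (fraction of frames at crest).
square_wave <- function(n_frames, duty, lo = 0, hi = 1) {
  period <- 20
  on_len <- round(duty * period)
  rep(c(rep(hi, on_len), rep(lo, period - on_len)), length.out = n_frames)
}

## Brute-force co-activity: direct double loop over pairs and frames.
brute_force_coactivity <- function(S) {
  n <- nrow(S)
  C <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    Ti <- sum(S[i, ]); Tj <- sum(S[j, ])
    Tij <- sum(S[i, ] == 1 & S[j, ] == 1)
    C[i, j] <- if (Ti > 0 && Tj > 0) Tij / sqrt(Ti * Tj) else 0
  }
  C
}

## Reference islet condition used for network-recovery checks.
reference_islet_config <- function(seed, duration_s = 360) {
  islet_sim_config(
    duration_s = duration_s,
    protocol = stim_protocol("glucose", 0, duration_s, 0.8),
    seed = seed)
}

## Full trace-to-hubs analysis used by the recovery checks.
analyze_islet <- function(dataset, n_permutations = 1000, alpha = 0.05,
                          perm_seed = 1) {
  den <- detrend_denoise(normalize_traces(dataset$traces))
  raster <- binarize_activity(den)
  co <- coactivity_matrix(raster)
  co <- permutation_significance(co, n_permutations = n_permutations,
                                 alpha = alpha, seed = perm_seed)
  hubs <- classify_hubs(co)
  list(denoised = den, raster = raster, coactivity = co, hubs = hubs)
}
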
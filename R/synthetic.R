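#' Configuration for the synthetic islet simulator
#'
#' Defines a simulated multicellular Ca2+ imaging experiment: a monolayer of
#' coupled bursting cells laid out in a disc, recorded at `frame_rate_hz` for
#' `duration_s` seconds under a stimulation protocol. A small planted
#' subpopulation of "hub" cells receives elevated connectivity in the coupling
#' graph and a boosted influence weight, so that downstream network inference
#' has a known ground truth to recover. Hubs are described in islet physiology
#' as a minority (~1-10%) of beta cells coordinating population activity;
#' `hub_fraction` plants them at a chosen prevalence.
#'
#' Cells follow a discrete-time two-state (quiescent/bursting) Markov model
#' with Erlang-shaped dwell times: each observable state is traversed through
#' `dwell_shape` internal substages, so dwell durations are gamma-distributed
#' with coefficient of variation `1/sqrt(dwell_shape)`. This reproduces the
#' quasi-regular fast Ca2+ oscillations of glucose-stimulated islets rather
#' than a memoryless telegraph process. The quiescent-to-bursting progression
#' rate grows with the epoch drive and with the weighted fraction of ON
#' neighbours; the bursting-to-quiescent rate is fixed.
#'
#' @param n_cells number of cells (positive integer).
#' @param hub_fraction fraction of cells planted as hubs, in `[0, 1]`.
#' @param coupling_strength non-negative coupling gain; 0 gives fully
#'   independent cells. The default is the package's reference coupling used
#'   throughout the examples.
#' @param frame_rate_hz acquisition rate in Hz (default 20, fast recording).
#' @param duration_s recording length in seconds.
#' @param noise_sd Gaussian measurement noise, as a fraction of the burst
#'   fluorescence amplitude.
#' @param drift_amplitude amplitude of the slow sinusoidal baseline drift,
#'   as a fraction of baseline fluorescence.
#' @param protocol a [stim_protocol()] table; default baseline then glucose.
#' @param seed integer RNG seed; the simulation is deterministic given it.
#' @param layout_radius radius of the cell layout disc (arbitrary units).
#' @param k_neighbors spatial k-nearest-neighbour count for ordinary cells.
#' @param hub_degree_fraction fraction of the population each hub is wired
#'   to (hubs get top-k degree in the coupling graph).
#' @param hub_weight_boost multiplicative influence weight of hub cells.
#' @param hub_drive_boost multiplier on the intrinsic ON rate of hubs, making
#'   them lead state transitions of their neighbourhoods.
#' @param hub_burst_boost multiplier on hub burst duration: hub activity
#'   spans the shorter bursts of the cells they recruit.
#' @param quiescent_s mean quiescent dwell at full drive without coupling
#'   (seconds).
#' @param burst_s mean burst duration (seconds).
#' @param dwell_shape Erlang shape of both dwell distributions (integer;
#'   1 recovers the memoryless two-state chain).
#' @param coupling_rate_hz additional ON-onset rate per unit drive at full
#'   neighbour influence and unit coupling strength (Hz).
#' @param ca_tau_s indicator on/off kinetic time constant used when
#'   rendering fluorescence (seconds; 0 for instantaneous).
#' @return An object of class `islet_sim_config`.
#' @seealso [generate_islet_traces()]
#' @export
islet_sim_config <- function(n_cells = 50,
                             hub_fraction = 0.1,
                             coupling_strength = 0.12,
                             frame_rate_hz = 20,
                             duration_s = 180,
                             noise_sd = 0.05,
                             drift_amplitude = 0.1,
                             protocol = default_protocol(duration_s),
                             seed = 1,
                             layout_radius = 100,
                             k_neighbors = 3,
                             hub_degree_fraction = 0.35,
                             hub_weight_boost = 10,
                             hub_drive_boost = 1.2,
                             hub_burst_boost = 6,
                             quiescent_s = 12,
                             burst_s = 1.5,
                             dwell_shape = 16,
                             coupling_rate_hz = 2,
                             ca_tau_s = 0.2) {
  check_scalar(n_cells, "n_cells", lower = 1, integer = TRUE)
  check_scalar(hub_fraction, "hub_fraction", lower = 0, upper = 1)
  check_scalar(coupling_strength, "coupling_strength", lower = 0)
  check_scalar(frame_rate_hz, "frame_rate_hz", lower = 1e-9)
  check_scalar(duration_s, "duration_s", lower = 1e-9)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(drift_amplitude, "drift_amplitude", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(layout_radius, "layout_radius", lower = 1e-9)
  check_scalar(k_neighbors, "k_neighbors", lower = 1, integer = TRUE)
  check_scalar(hub_degree_fraction, "hub_degree_fraction", lower = 0, upper = 1)
  check_scalar(hub_weight_boost, "hub_weight_boost", lower = 1)
  check_scalar(hub_drive_boost, "hub_drive_boost", lower = 1)
  check_scalar(hub_burst_boost, "hub_burst_boost", lower = 1)
  check_scalar(quiescent_s, "quiescent_s", lower = 1e-9)
  check_scalar(burst_s, "burst_s", lower = 1e-9)
  check_scalar(dwell_shape, "dwell_shape", lower = 1, integer = TRUE)
  check_scalar(coupling_rate_hz, "coupling_rate_hz", lower = 0)
  check_scalar(ca_tau_s, "ca_tau_s", lower = 0)
  if (!inherits(protocol, "stim_protocol")) {
    stop_config("protocol", "must be a stim_protocol table")
  }
  if (frame_rate_hz * duration_s < 2) {
    stop_config("duration_s", "recording must contain at least 2 frames")
  }
  structure(list(
    n_cells = as.integer(n_cells), hub_fraction = hub_fraction,
    coupling_strength = coupling_strength, frame_rate_hz = frame_rate_hz,
    duration_s = duration_s, noise_sd = noise_sd,
    drift_amplitude = drift_amplitude, protocol = protocol,
    seed = as.integer(seed), layout_radius = layout_radius,
    k_neighbors = as.integer(k_neighbors),
    hub_degree_fraction = hub_degree_fraction,
    hub_weight_boost = hub_weight_boost, hub_drive_boost = hub_drive_boost,
    hub_burst_boost = hub_burst_boost,
    quiescent_s = quiescent_s, burst_s = burst_s,
    dwell_shape = as.integer(dwell_shape),
    coupling_rate_hz = coupling_rate_hz, ca_tau_s = ca_tau_s
  ), class = "islet_sim_config")
}

#' Construct a fluorescence trace set
#'
#' The cell-by-frame container used throughout the package: a rectangular
#' matrix of fluorescence values plus acquisition metadata (frame rate, cell
#' identifiers, Euclidean ROI coordinates, stimulation protocol).
#'
#' @param values numeric cell x frame matrix; all values must be finite.
#' @param frame_rate_hz acquisition rate in Hz.
#' @param cell_ids character or integer identifiers, one per row.
#' @param coords data.frame with columns `x`, `y`, one row per cell, or NULL.
#' @param epochs a [stim_protocol()] table or NULL.
#' @return An object of class `fluorescence_traces`.
#' @export
fluorescence_traces <- function(values, frame_rate_hz, cell_ids = NULL,
                                coords = NULL, epochs = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("trace values must all be finite")
  check_scalar(frame_rate_hz, "frame_rate_hz", lower = 1e-9)
  n <- nrow(values)
  cell_ids <- cell_ids %||% sprintf("cell_%03d", seq_len(n))
  if (length(cell_ids) != n) stop("cell_ids length must match rows of values")
  if (!is.null(coords)) {
    if (nrow(coords) != n || !all(c("x", "y") %in% names(coords))) {
      stop("coords must have one (x, y) row per cell")
    }
  }
  rownames(values) <- cell_ids
  structure(list(values = values, frame_rate_hz = frame_rate_hz,
                 cell_ids = cell_ids, coords = coords, epochs = epochs),
            class = "fluorescence_traces")
}

#' @export
print.fluorescence_traces <- function(x, ...) {
  cat(sprintf("fluorescence_traces: %d cells x %d frames @ %g Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$frame_rate_hz,
              ncol(x$values) / x$frame_rate_hz))
  if (!is.null(x$epochs)) {
    cat("protocol:", paste(sprintf("%s[%g-%gs]", x$epochs$label,
                                   x$epochs$start_s, x$epochs$end_s),
                           collapse = " "), "\n")
  }
  invisible(x)
}

#' Time axis of a trace set
#' @param traces a `fluorescence_traces` or `normalized_traces` object.
#' @return Numeric vector of frame times in seconds (first frame at 0).
#' @export
trace_times <- function(traces) {
  (seq_len(ncol(traces$values)) - 1) / traces$frame_rate_hz
}

## Undirected coupling graph: union of kNN edges; hubs additionally wired to
## a hub_degree_fraction of the population. Returns receiver-normalised
## influence weight matrix W (rows = receivers) and the adjacency used.
build_coupling_graph <- function(coords, hubs, cfg) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  adj <- matrix(FALSE, n, n)
  k <- min(cfg$k_neighbors, n - 1)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]
    adj[i, nb] <- TRUE
    adj[nb, i] <- TRUE
  }
  k_hub <- min(n - 1, max(k, round(cfg$hub_degree_fraction * n)))
  for (h in which(hubs)) {
    nb <- order(D[h, ])[seq_len(k_hub)]
    adj[h, nb] <- TRUE
    adj[nb, h] <- TRUE
  }
  ## Influence of source j on receiver i; scaled so a single bursting hub
  ## saturates a follower's influence at 1, while an ordinary neighbour
  ## contributes only 1/hub_weight_boost.
  src_w <- ifelse(hubs, cfg$hub_weight_boost, 1)
  W <- adj * rep(src_w, each = n) / cfg$hub_weight_boost
  list(W = W, adj = adj)
}

#' Simulate a synthetic islet Ca2+ recording
#'
#' Runs the staged two-state Markov burster model described in
#' [islet_sim_config()] on a spatial proximity graph with planted hub cells,
#' and renders fluorescence as
#' `baseline * (1 + drift) + amplitude * kinetics(state) + noise`, where
#' `kinetics` is an exponential indicator filter with time constant
#' `ca_tau_s` (the dye/sensor does not switch instantaneously). KCl epochs
#' force all cells ON (depolarisation); "silenced" epochs multiply the
#' ON-transition probability by the epoch drive level (partial suppression,
#' as under chemogenetic inhibition). The noiseless binary state sequence is
#' returned as the ground-truth raster, and the planted hub identities as a
#' logical vector.
#'
#' @param config an [islet_sim_config()].
#' @return An object of class `synthetic_islet`: a list with elements
#'   `traces` ([fluorescence_traces()]), `truth_raster` ([binary_raster()]),
#'   `truth_hubs` (logical per cell), and `config`.
#' @examples
#' d <- generate_islet_traces(islet_sim_config(n_cells = 20, duration_s = 30))
#' d
#' @export
generate_islet_traces <- function(config) {
  if (!inherits(config, "islet_sim_config")) {
    config <- do.call(islet_sim_config, config)
  }
  cfg <- config
  n <- cfg$n_cells
  dt <- 1 / cfg$frame_rate_hz
  n_frames <- floor(cfg$frame_rate_hz * cfg$duration_s)
  times <- (seq_len(n_frames) - 1) * dt
  ep <- epoch_frame_drive(cfg$protocol, times)

  with_seed(cfg$seed, {
    ## disc layout, uniform by area
    r <- cfg$layout_radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    coords <- data.frame(x = r * cos(th), y = r * sin(th))

    ## hubs are spatially spread (farthest-point sampling from a random
    ## start), so their follower territories tile the islet
    n_hubs <- round(cfg$hub_fraction * n)
    hubs <- rep(FALSE, n)
    if (n_hubs > 0) {
      picked <- sample.int(n, 1)
      while (length(picked) < n_hubs) {
        D2 <- outer(coords$x, coords$x[picked], `-`)^2 +
          outer(coords$y, coords$y[picked], `-`)^2
        cand <- which.max(apply(D2, 1, min))
        picked <- c(picked, cand)
      }
      hubs[picked] <- TRUE
    }

    graph <- build_coupling_graph(coords, hubs, cfg)
    W <- graph$W

    drive_mult <- ifelse(hubs, cfg$hub_drive_boost, 1)
    k_sh <- cfg$dwell_shape
    burst_dur <- cfg$burst_s * ifelse(hubs, cfg$hub_burst_boost, 1)
    p_off_stage <- 1 - exp(-dt * k_sh / burst_dur)

    states <- matrix(0L, n, n_frames)
    s <- integer(n)
    stage <- rep(1L, n)
    for (t in seq_len(n_frames)) {
      lab <- ep$label[t]
      if (identical(lab, "kcl")) {
        s <- rep(1L, n); stage <- rep(1L, n)
      } else {
        drv <- if (identical(lab, "silenced")) 1 else ep$drive[t]
        infl <- as.numeric(W %*% s)
        onset_rate <- drive_mult * drv *
          (1 / cfg$quiescent_s +
             cfg$coupling_rate_hz * cfg$coupling_strength * infl)
        p_adv <- ifelse(s == 1L, p_off_stage,
                        1 - exp(-dt * k_sh * onset_rate))
        if (identical(lab, "silenced")) {
          p_adv <- ifelse(s == 1L, p_adv, p_adv * ep$drive[t])
        }
        adv <- stats::runif(n) < p_adv
        flip <- adv & stage == k_sh
        stage <- ifelse(adv, ifelse(flip, 1L, stage + 1L), stage)
        s <- ifelse(flip, 1L - s, s)
      }
      states[, t] <- s
    }

    baseline <- stats::runif(n, 0.9, 1.1)
    amplitude <- stats::runif(n, 0.9, 1.1)
    phase <- stats::runif(n, 0, 2 * pi)
    drift_period <- cfg$duration_s           # one slow cycle per recording
    drift <- cfg$drift_amplitude *
      sin(outer(phase, 2 * pi * times / drift_period, `+`))
    signal <- if (cfg$ca_tau_s > 0) {
      a <- exp(-1 / (cfg$frame_rate_hz * cfg$ca_tau_s))
      t(apply(states, 1, function(z) {
        as.numeric(stats::filter(z * (1 - a), a, method = "recursive"))
      }))
    } else {
      states
    }
    F <- baseline * (1 + drift) + amplitude * signal +
      matrix(stats::rnorm(n * n_frames, sd = cfg$noise_sd), n) * amplitude

    traces <- fluorescence_traces(F, cfg$frame_rate_hz, coords = coords,
                                  epochs = cfg$protocol)
    truth <- binary_raster(states, threshold_fraction = NA_real_)
    rownames(truth$states) <- traces$cell_ids
    structure(list(traces = traces, truth_raster = truth,
                   truth_hubs = hubs, config = cfg),
              class = "synthetic_islet")
  })
}

#' @export
print.synthetic_islet <- function(x, ...) {
  cat(sprintf("synthetic_islet: %d cells (%d planted hubs), %d frames @ %g Hz\n",
              x$config$n_cells, sum(x$truth_hubs),
              ncol(x$traces$values), x$config$frame_rate_hz))
  invisible(x)
}

#' Configuration for the synthetic nuclei-stain image generator
#'
#' Describes a 2-D immunofluorescence image of well-separated Gaussian nuclei
#' over a constant background, with per-cell peak intensities drawn from a
#' two-component (LOW/HIGH) mixture. This emulates transcription-factor
#' (PDX1/MAFA) staining in which an immature LOW population and a mature HIGH
#' population produce a bimodal per-cell intensity distribution.
#'
#' @param n_cells number of nuclei to place.
#' @param low_fraction fraction of cells drawn from the LOW component.
#' @param low_mean,high_mean mean peak intensity of each component (arbitrary
#'   units above background); `low_mean < high_mean` required.
#' @param low_sd,high_sd component standard deviations.
#' @param background_level constant background intensity.
#' @param nucleus_sigma_px Gaussian radius of each nucleus in pixels.
#' @param image_shape integer vector `c(rows, cols)` in pixels.
#' @param noise_sd additive Gaussian pixel noise (intensity units).
#' @param seed integer RNG seed.
#' @return An object of class `stain_sim_config`.
#' @export
stain_sim_config <- function(n_cells = 30,
                             low_fraction = 0.2,
                             low_mean = 7000, high_mean = 15000,
                             low_sd = 600, high_sd = 2000,
                             background_level = 500,
                             nucleus_sigma_px = 5,
                             image_shape = c(256, 256),
                             noise_sd = 30,
                             seed = 1) {
  check_scalar(n_cells, "n_cells", lower = 1, integer = TRUE)
  check_scalar(low_fraction, "low_fraction", lower = 0, upper = 1)
  check_scalar(low_mean, "low_mean", lower = 0)
  check_scalar(high_mean, "high_mean", lower = 0)
  check_scalar(low_sd, "low_sd", lower = 0)
  check_scalar(high_sd, "high_sd", lower = 0)
  check_scalar(background_level, "background_level", lower = 0)
  check_scalar(nucleus_sigma_px, "nucleus_sigma_px", lower = 1e-9)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  if (low_mean >= high_mean) stop_config("low_mean", "must be < high_mean")
  if (length(image_shape) != 2 || any(image_shape < 8)) {
    stop_config("image_shape", "must be two pixel dimensions >= 8")
  }
  structure(list(n_cells = as.integer(n_cells), low_fraction = low_fraction,
                 low_mean = low_mean, high_mean = high_mean,
                 low_sd = low_sd, high_sd = high_sd,
                 background_level = background_level,
                 nucleus_sigma_px = nucleus_sigma_px,
                 image_shape = as.integer(image_shape),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "stain_sim_config")
}

#' Simulate a nuclei-stain image with known per-cell intensities
#'
#' Places `n_cells` Gaussian nuclei in the image with a minimum
#' centre-to-centre separation of four nucleus radii (well-separated regime),
#' draws each peak intensity from the LOW/HIGH mixture, and renders the image
#' over a constant background with optional pixel noise. The ground-truth
#' table records each nucleus' centre, radius, true class, planted peak and
#' the analytic mean intensity over its full-width-half-maximum disc (the
#' region a per-cell half-maximum measurement recovers).
#'
#' @param config a [stain_sim_config()].
#' @return A list of class `synthetic_stain`: `image` (numeric matrix,
#'   intensity units), `cells` (ground-truth data.frame with columns
#'   `cell_id`, `x`, `y`, `radius_px`, `class`, `peak`, `true_mean`),
#'   and `config`.
#' @export
generate_stain_image <- function(config) {
  if (!inherits(config, "stain_sim_config")) {
    config <- do.call(stain_sim_config, config)
  }
  cfg <- config
  sigma <- cfg$nucleus_sigma_px
  min_sep <- 4 * sigma
  margin <- ceiling(3 * sigma) + 1
  nr <- cfg$image_shape[1]; nc <- cfg$image_shape[2]
  if (nr - 2 * margin < 1 || nc - 2 * margin < 1) {
    stop("image too small for the requested nucleus size", call. = FALSE)
  }

  with_seed(cfg$seed, {
    ## greedy rejection placement at the required separation
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < cfg$n_cells) {
      tries <- tries + 1L
      if (tries > 200L * cfg$n_cells) {
        stop(sprintf(
          "cannot place %d nuclei at separation %.1f px in a %dx%d image",
          cfg$n_cells, min_sep, nr, nc), call. = FALSE)
      }
      x <- stats::runif(1, margin, nc - margin)
      y <- stats::runif(1, margin, nr - margin)
      if (length(xs) == 0 ||
          min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_sep) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }

    is_low <- stats::runif(cfg$n_cells) < cfg$low_fraction
    peak <- ifelse(is_low,
                   stats::rnorm(cfg$n_cells, cfg$low_mean, cfg$low_sd),
                   stats::rnorm(cfg$n_cells, cfg$high_mean, cfg$high_sd))
    peak <- pmax(peak, 0)

    img <- matrix(cfg$background_level, nr, nc)
    for (i in seq_len(cfg$n_cells)) {
      rows <- max(1, floor(ys[i] - 4 * sigma)):min(nr, ceiling(ys[i] + 4 * sigma))
      cols <- max(1, floor(xs[i] - 4 * sigma)):min(nc, ceiling(xs[i] + 4 * sigma))
      g <- exp(-(outer((rows - ys[i])^2, (cols - xs[i])^2, `+`)) / (2 * sigma^2))
      img[rows, cols] <- img[rows, cols] + peak[i] * g
    }
    if (cfg$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(nr * nc, sd = cfg$noise_sd), nr, nc)
    }
    img <- pmax(img, 0)

    ## mean of bg + peak * g over the disc where g >= 1/2 is
    ## bg + peak * (1 - 1/2) / ln 2
    true_mean <- cfg$background_level + peak * (0.5 / log(2))
    cells <- data.frame(cell_id = seq_len(cfg$n_cells), x = xs, y = ys,
                        radius_px = sigma * sqrt(2 * log(2)),
                        class = ifelse(is_low, "LOW", "HIGH"),
                        peak = peak, true_mean = true_mean,
                        stringsAsFactors = FALSE)
    structure(list(image = img, cells = cells, config = cfg),
              class = "synthetic_stain")
  })
}

#' @export
print.synthetic_stain <- function(x, ...) {
  cat(sprintf("synthetic_stain: %dx%d image, %d nuclei (%d LOW / %d HIGH)\n",
              nrow(x$image), ncol(x$image), nrow(x$cells),
              sum(x$cells$class == "LOW"), sum(x$cells$class == "HIGH")))
  invisible(x)
}
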
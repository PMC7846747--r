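#' Segment and measure stained cells in a 2-D image
#'
#' ImageJ-style per-cell quantification: the image is Gaussian filtered,
#' auto-thresholded (Otsu by default) and binarized into a mask; connected
#' components (optionally split by a distance-transform watershed) above a
#' minimum area become cells. Mean intensity is always measured on the
#' original, unfiltered image — the filter only builds the mask. By default
#' each component's measurement region is refined to the pixels above the
#' component's half-maximum (over the background estimate), so the reported
#' mean does not depend on where the global threshold happens to cut each
#' nucleus' intensity profile; set `refine = "mask"` to measure over the raw
#' mask instead.
#'
#' @param image numeric matrix (single-channel 2-D image, intensity units).
#' @param sigma Gaussian filter radius in pixels.
#' @param threshold_method `"otsu"` (automatic) or a numeric threshold in
#'   intensity units.
#' @param min_area_px minimum component area in pixels.
#' @param watershed split touching components with a distance-transform
#'   watershed (default TRUE).
#' @param refine `"halfmax"` (default) or `"mask"`; see Details.
#' @param channel optional label stored with the table.
#' @param image_id optional image identifier stored with the table.
#' @return A data.frame of class `cell_intensity_table` with columns
#'   `cell_id`, `x`, `y` (centroid, pixels), `area_px`, `mean_intensity`,
#'   `max_intensity`, `channel`, `image_id`. Empty (with a warning) when
#'   the mask contains no objects.
#' @export
measure_cells <- function(image, sigma = 2, threshold_method = "otsu",
                          min_area_px = 20, watershed = TRUE,
                          refine = c("halfmax", "mask"),
                          channel = NA_character_, image_id = NA_character_) {
  refine <- match.arg(refine)
  image <- as.matrix(image)
  if (any(!is.finite(image))) stop("image must be finite", call. = FALSE)

  ## EBImage works on [0, 1]; scale by the image max
  mx <- max(image)
  if (mx <= 0 || diff(range(image)) == 0) {
    warning("blank image: empty mask")
    return(empty_cell_table(channel, image_id))
  }
  im01 <- EBImage::Image(image / mx)
  sm <- EBImage::gblur(im01, sigma = sigma)
  thr <- if (identical(threshold_method, "otsu")) {
    EBImage::otsu(sm, range = c(0, 1))
  } else {
    as.numeric(threshold_method) / mx
  }
  mask <- sm > thr
  if (sum(mask) == 0) {
    warning("empty mask after thresholding")
    return(empty_cell_table(channel, image_id))
  }
  labels <- if (watershed) {
    EBImage::watershed(EBImage::distmap(mask))
  } else {
    EBImage::bwlabel(mask)
  }
  lab <- EBImage::imageData(labels)
  bg_mean <- mean(image[lab == 0])

  ids <- setdiff(sort(unique(as.vector(lab))), 0)
  rows <- list()
  for (id in ids) {
    sel <- which(lab == id, arr.ind = TRUE)
    if (nrow(sel) < min_area_px) next
    vals <- image[sel]
    if (refine == "halfmax") {
      ## the Otsu mask of a dim cell can be smaller than its half-max
      ## region: search a padded window around the component, excluding
      ## pixels owned by other components
      pad <- 2L + ceiling(sqrt(nrow(sel) / pi))
      rr <- max(1, min(sel[, 1]) - pad):min(nrow(image), max(sel[, 1]) + pad)
      cc <- max(1, min(sel[, 2]) - pad):min(ncol(image), max(sel[, 2]) + pad)
      win_lab <- lab[rr, cc]
      cand <- which(win_lab == id | win_lab == 0, arr.ind = TRUE)
      cand[, 1] <- rr[cand[, 1]]; cand[, 2] <- cc[cand[, 2]]
      cut <- bg_mean + 0.5 * (max(vals) - bg_mean)
      keep <- image[cand] >= cut
      sel <- cand[keep, , drop = FALSE]
      vals <- image[sel]
    }
    rows[[length(rows) + 1]] <- data.frame(
      x = mean(sel[, 2]), y = mean(sel[, 1]),       # col = x, row = y
      area_px = nrow(sel), mean_intensity = mean(vals),
      max_intensity = max(vals))
  }
  if (!length(rows)) {
    warning("no components above the minimum area")
    return(empty_cell_table(channel, image_id))
  }
  out <- do.call(rbind, rows)
  out <- cbind(cell_id = seq_len(nrow(out)), out,
               channel = channel, image_id = image_id,
               stringsAsFactors = FALSE)
  class(out) <- c("cell_intensity_table", "data.frame")
  out
}

empty_cell_table <- function(channel, image_id) {
  out <- data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                    area_px = numeric(0), mean_intensity = numeric(0),
                    max_intensity = numeric(0),
                    channel = character(0), image_id = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_intensity_table", "data.frame")
  out
}

#' Normalized per-cell intensity distribution
#'
#' Maps per-cell mean intensities onto a 0-100 normalized scale and bins
#' them into 21 half-open width-5 bins `[0,5), ..., [100,105)`, reporting
#' each bin's percentage of cells. The default normalization maps the 1st
#' and 99th percentiles of the pooled intensities linearly to 0 and 100
#' with clipping; `"minmax"` uses the pooled minimum/maximum; `"to_ref"`
#' divides by a matched reference vector (e.g. a DAPI channel) before the
#' linear map. The LOW fraction is the percentage of cells below
#' `low_cutoff_units` (15 by default: exactly the bottom three bins).
#'
#' @param intensities numeric vector of per-cell intensities, or a
#'   [measure_cells()] table (its `mean_intensity` column is used).
#' @param normalization `"p1p99"`, `"minmax"`, or `"to_ref"`.
#' @param ref reference intensities for `"to_ref"`.
#' @param low_cutoff_units cutoff on the normalized scale, default 15.
#' @return An object of class `intensity_distribution`: list with
#'   `normalized` (per-cell values, 0-100), `bin_edges` (length 22),
#'   `frequency_percent` (length 21, sums to 100), `low_cutoff_units`,
#'   `low_fraction` (percent of cells below the cutoff), `normalization`.
#' @export
intensity_distribution <- function(intensities,
                                   normalization = c("p1p99", "minmax", "to_ref"),
                                   ref = NULL, low_cutoff_units = 15) {
  normalization <- match.arg(normalization)
  if (inherits(intensities, "cell_intensity_table")) {
    intensities <- intensities$mean_intensity
  }
  x <- as.numeric(intensities)
  if (!length(x)) stop("at least one cell required", call. = FALSE)
  if (normalization == "to_ref") {
    if (is.null(ref) || length(ref) != length(x)) {
      stop("to_ref normalization needs a matched reference vector", call. = FALSE)
    }
    x <- x / ref
  }
  rng <- switch(normalization,
                minmax = range(x),
                stats::quantile(x, c(0.01, 0.99), names = FALSE))
  if (diff(rng) <= 0) stop("degenerate intensity range", call. = FALSE)
  norm <- clamp(100 * (x - rng[1]) / (rng[2] - rng[1]), 0, 100)

  edges <- seq(0, 105, by = 5)
  counts <- vapply(seq_len(21), function(b) {
    sum(norm >= edges[b] & norm < edges[b + 1])
  }, numeric(1))
  freq <- 100 * counts / length(norm)
  low_fraction <- 100 * mean(norm < low_cutoff_units)
  structure(list(normalized = norm, bin_edges = edges,
                 frequency_percent = freq,
                 low_cutoff_units = low_cutoff_units,
                 low_fraction = low_fraction,
                 normalization = normalization),
            class = "intensity_distribution")
}

#' @export
print.intensity_distribution <- function(x, ...) {
  cat(sprintf("intensity_distribution: %d cells, %.1f%% below %g normalized units\n",
              length(x$normalized), x$low_fraction, x$low_cutoff_units))
  invisible(x)
}

#' Plot a normalized intensity frequency distribution
#' @param x an `intensity_distribution`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.intensity_distribution <- function(x, ...) {
  mids <- x$bin_edges[-22] + 2.5
  cols <- ifelse(x$bin_edges[-22] < x$low_cutoff_units, "tomato", "steelblue")
  graphics::barplot(x$frequency_percent, names.arg = mids, col = cols,
                    xlab = "normalized intensity (units)",
                    ylab = "% of cells", ...)
  invisible(x)
}

#' Classify cells as LOW or HIGH maturity
#'
#' Cells below `cutoff_units` on the 0-100 normalized intensity scale are
#' LOW (immature); cells at or above it are HIGH. The boundary is half-open:
#' a cell at exactly the cutoff is HIGH.
#'
#' @param dist an [intensity_distribution()] (or numeric normalized values).
#' @param cutoff_units normalized-unit cutoff, default 15.
#' @return A list of class `maturity_classification`: `labels` (factor
#'   LOW/HIGH per cell), `low_fraction` (percent LOW), `cutoff_units`.
#' @export
classify_maturity <- function(dist, cutoff_units = 15) {
  norm <- if (inherits(dist, "intensity_distribution")) dist$normalized else
    as.numeric(dist)
  labels <- factor(ifelse(norm < cutoff_units, "LOW", "HIGH"),
                   levels = c("LOW", "HIGH"))
  structure(list(labels = labels, low_fraction = 100 * mean(labels == "LOW"),
                 cutoff_units = cutoff_units),
            class = "maturity_classification")
}

#' @export
print.maturity_classification <- function(x, ...) {
  cat(sprintf("maturity: %d LOW / %d HIGH (%.1f%% LOW, cutoff %g units)\n",
              sum(x$labels == "LOW"), sum(x$labels == "HIGH"),
              x$low_fraction, x$cutoff_units))
  invisible(x)
}

#' Corrected total cell fluorescence
#'
#' \deqn{CTCF = \mathrm{integrated\ density} - \mathrm{area\ of\ ROI}
#'   \times \mathrm{mean\ background\ fluorescence}}
#' computed exactly. Negative values are permitted and flagged (they arise
#' when the cell is dimmer than the background estimate).
#'
#' @param integrated_density sum of pixel intensities over the ROI.
#' @param roi_area ROI area (pixels or um^2; must be > 0).
#' @param background_mean mean background fluorescence per unit area.
#' @return A data.frame of class `ctcf_record` with columns
#'   `integrated_density`, `roi_area`, `background_mean`, `ctcf`,
#'   `negative` (flag). Vectorised over its arguments.
#' @examples
#' ctcf(1000, 50, 2)$ctcf  # 900
#' @export
ctcf <- function(integrated_density, roi_area, background_mean) {
  if (any(roi_area <= 0)) stop("roi_area must be positive", call. = FALSE)
  val <- integrated_density - roi_area * background_mean
  out <- data.frame(integrated_density = integrated_density,
                    roi_area = roi_area, background_mean = background_mean,
                    ctcf = val, negative = val < 0)
  class(out) <- c("ctcf_record", "data.frame")
  out
}

#' Relative expression fold change (2^-ddCt)
#'
#' Standard qPCR relative quantification: the target gene's cycle threshold
#' is referenced to a housekeeping gene within each condition, and the
#' case-vs-control difference of those deltas is exponentiated:
#' \deqn{\Delta\Delta Ct = (Ct^{target}_{case} - Ct^{ref}_{case}) -
#'   (Ct^{target}_{ctrl} - Ct^{ref}_{ctrl}), \quad
#'   \mathrm{fold} = 2^{-\Delta\Delta Ct}.}
#'
#' @param ct_target_case,ct_ref_case target and reference Ct in the case
#'   condition.
#' @param ct_target_ctrl,ct_ref_ctrl the same in the control condition.
#' @return Numeric fold change (vectorised).
#' @examples
#' fold_change_ddct(20, 15, 21, 15)  # one cycle lower in case -> 2
#' @export
fold_change_ddct <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(all(is.finite(c(ct_target_case, ct_ref_case,
                            ct_target_ctrl, ct_ref_ctrl))))
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
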
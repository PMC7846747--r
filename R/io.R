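## File interfaces. Trace CSV dialect: columns cell_id, x, y, then one column
## per frame headed by its time in seconds (prefixed "t" to stay a valid
## column name). Rasters are 0/1 CSVs in the same layout.

#' Write a trace set to CSV
#' @param traces a `fluorescence_traces` or `normalized_traces` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  tt <- trace_times(traces)
  co <- traces$coords %||% data.frame(x = rep(NA_real_, nrow(traces$values)),
                                      y = NA_real_)
  df <- data.frame(cell_id = traces$cell_ids, x = signif9(co$x),
                   y = signif9(co$y), signif9(traces$values))
  names(df)[-(1:3)] <- sprintf("t%.9g", tt)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace set from CSV
#' @param path CSV written by [write_traces_csv()].
#' @param frame_rate_hz frame rate; inferred from the time header if NULL.
#' @param epochs optional [stim_protocol()] to attach.
#' @return A `fluorescence_traces` object.
#' @export
read_traces_csv <- function(path, frame_rate_hz = NULL, epochs = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  tcols <- grep("^t", names(df))
  tt <- as.numeric(sub("^t", "", names(df)[tcols]))
  if (is.null(frame_rate_hz)) {
    frame_rate_hz <- 1 / stats::median(diff(tt))
  }
  V <- as.matrix(df[, tcols])
  coords <- if (all(is.finite(df$x))) data.frame(x = df$x, y = df$y) else NULL
  fluorescence_traces(V, frame_rate_hz, cell_ids = as.character(df$cell_id),
                      coords = coords, epochs = epochs)
}

#' Write a binary raster to CSV
#' @param raster a [binary_raster()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(raster, path) {
  df <- data.frame(cell_id = rownames(raster$states) %||%
                     sprintf("cell_%03d", seq_len(nrow(raster$states))),
                   raster$states)
  names(df)[-1] <- sprintf("f%d", seq_len(ncol(raster$states)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a binary raster from CSV
#' @param path CSV written by [write_raster_csv()].
#' @return A [binary_raster()].
#' @export
read_raster_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  S <- as.matrix(df[, -1])
  rownames(S) <- df$cell_id
  binary_raster(S)
}

#' Write an intensity image as 16-bit TIFF
#' @param image numeric matrix in intensity units.
#' @param path output path.
#' @param max_value full-scale intensity mapped to 65535.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, max_value = 65535) {
  m <- clamp(image / max_value, 0, 1)
  tiff::writeTIFF(m, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a single-plane TIFF as an intensity matrix
#' @param path TIFF path.
#' @param max_value intensity corresponding to full scale.
#' @return Numeric matrix.
#' @export
read_image_tiff <- function(path, max_value = 65535) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m * max_value
}

#' Extract ROI mean-intensity traces from an image stack
#'
#' For time-lapse data supplied as a frame stack plus an ROI table, returns
#' the per-frame mean intensity inside each circular ROI.
#'
#' @param stack list of numeric matrices (one per frame) or 3-D array
#'   (rows x cols x frames).
#' @param rois data.frame with `cell_id`, `x`, `y`, `radius_px`.
#' @param frame_rate_hz acquisition rate.
#' @param epochs optional [stim_protocol()].
#' @return A `fluorescence_traces` object.
#' @export
extract_roi_traces <- function(stack, rois, frame_rate_hz, epochs = NULL) {
  if (is.array(stack) && length(dim(stack)) == 3) {
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  }
  nr <- nrow(stack[[1]]); nc <- ncol(stack[[1]])
  masks <- lapply(seq_len(nrow(rois)), function(i) {
    dx <- outer(rep(1, nr), seq_len(nc) - rois$x[i])
    dy <- outer(seq_len(nr) - rois$y[i], rep(1, nc))
    which(dx^2 + dy^2 <= rois$radius_px[i]^2)
  })
  V <- vapply(stack, function(fr) {
    vapply(masks, function(m) mean(fr[m]), numeric(1))
  }, numeric(nrow(rois)))
  fluorescence_traces(matrix(V, nrow = nrow(rois)), frame_rate_hz,
                      cell_ids = as.character(rois$cell_id),
                      coords = data.frame(x = rois$x, y = rois$y),
                      epochs = epochs)
}

#' Write a connectivity map as node and edge CSVs
#' @param map a [build_connectivity_map()] result.
#' @param node_path,edge_path output CSV paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_connectivity_map <- function(map, node_path, edge_path) {
  nodes <- map$nodes
  nodes$x <- signif9(nodes$x); nodes$y <- signif9(nodes$y)
  nodes$link_percent <- signif9(nodes$link_percent)
  utils::write.csv(nodes, node_path, row.names = FALSE)
  edges <- map$edges
  if (nrow(edges)) {
    edges$C <- signif9(edges$C); edges$p <- signif9(edges$p)
  }
  utils::write.csv(edges, edge_path, row.names = FALSE)
  invisible(list(nodes = node_path, edges = edge_path))
}
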
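#' Pairwise co-activity matrix from a binary raster
#'
#' For each unordered cell pair the co-activity coefficient is
#' \deqn{C_{ij} = T_{ij} / \sqrt{T_i T_j}}
#' where \eqn{T_i} and \eqn{T_j} are the number of frames each cell spends
#' ON and \eqn{T_{ij}} the number of frames both are ON together. C ranges
#' from 0 (never co-active) to 1 (identical ON periods). Pairs involving a
#' cell that is never ON are assigned C = 0 and the cell is flagged
#' inactive; the diagonal is excluded (NA).
#'
#' @param raster a [binary_raster()].
#' @return An object of class `coactivity`: list with `C` (symmetric
#'   matrix), `T_on` (per-cell ON counts), `T_joint` (joint ON count
#'   matrix), `active` (logical per cell), and placeholders for the
#'   permutation results (`p_values`, `adjacency`, `alpha`,
#'   `n_permutations`), filled by [permutation_significance()].
#' @examples
#' r <- binary_raster(rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 0)))
#' coactivity_matrix(r)$C
#' @export
coactivity_matrix <- function(raster) {
  S <- raster$states
  if (nrow(S) < 1 || ncol(S) < 1) stop("empty raster", call. = FALSE)
  T_on <- rowSums(S)
  TJ <- tcrossprod(S)                       # T_joint[i, j]
  denom <- sqrt(outer(T_on, T_on))
  C <- ifelse(denom > 0, TJ / denom, 0)
  diag(C) <- NA_real_
  active <- T_on > 0
  ids <- rownames(S) %||% sprintf("cell_%03d", seq_len(nrow(S)))
  dimnames(C) <- list(ids, ids)
  structure(list(C = C, T_on = T_on, T_joint = TJ, active = active,
                 cell_ids = ids, n_frames = ncol(S), raster = raster,
                 p_values = NULL, adjacency = NULL, alpha = NA_real_,
                 n_permutations = NA_integer_),
            class = "coactivity")
}

#' @export
print.coactivity <- function(x, ...) {
  cat(sprintf("coactivity: %d cells (%d active), %d frames\n",
              length(x$T_on), sum(x$active), x$n_frames))
  if (!is.null(x$adjacency)) {
    cat(sprintf("significant links: %d pairs at alpha = %g (N = %d permutations)\n",
                sum(x$adjacency[upper.tri(x$adjacency)]), x$alpha,
                x$n_permutations))
  }
  invisible(x)
}

## Circularly shift each row of S by its own offset (vectorised).
shift_rows <- function(S, offsets) {
  n_frames <- ncol(S)
  col_idx <- outer(offsets, seq_len(n_frames), function(o, j) {
    ((j - 1 + o) %% n_frames) + 1
  })
  out <- matrix(S[cbind(rep(seq_len(nrow(S)), n_frames), as.vector(col_idx))],
                nrow(S), n_frames)
  out
}

#' Permutation significance of co-activity links
#'
#' Builds a null distribution for each pair by randomizing the binarized
#' row of every cell independently and recomputing the co-activity. The
#' default scheme applies an independent random circular shift to each row,
#' preserving each cell's burst-length structure while destroying cross-cell
#' alignment; `"full_shuffle"` permutes frames within each row instead.
#' Since \eqn{T_i} is invariant under both schemes, comparing null and
#' observed \eqn{T_{ij}} is exact. The p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{C^{null} \ge C^{obs}\}) / (1 + N)}, so the smallest
#' attainable value is \eqn{1/(N+1)}. No multiple-testing correction is
#' applied by default; Benjamini-Hochberg is available via `adjust`.
#'
#' @param coact a [coactivity_matrix()] result (carries the raster).
#' @param n_permutations number of randomized datasets, >= 100.
#' @param alpha significance level for calling a link.
#' @param seed RNG seed; results are deterministic given it.
#' @param scheme `"circular_shift"` (default) or `"full_shuffle"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return The `coactivity` object with `p_values`, `adjacency`, `alpha`,
#'   `n_permutations` filled in. Inactive cells get p = 1 and no links.
#' @export
permutation_significance <- function(coact, n_permutations = 1000,
                                     alpha = 0.05, seed = NULL,
                                     scheme = c("circular_shift", "full_shuffle"),
                                     adjust = c("none", "BH")) {
  scheme <- match.arg(scheme)
  adjust <- match.arg(adjust)
  stopifnot(inherits(coact, "coactivity"))
  if (n_permutations < 100) stop("n_permutations must be >= 100", call. = FALSE)
  S <- coact$raster$states
  n <- nrow(S); n_frames <- ncol(S)
  TJ_obs <- coact$T_joint
  cnt <- matrix(0L, n, n)
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      Sp <- if (scheme == "circular_shift") {
        shift_rows(S, sample.int(n_frames, n, replace = TRUE) - 1L)
      } else {
        t(apply(S, 1, sample))
      }
      cnt <- cnt + (tcrossprod(Sp) >= TJ_obs)
    }
  })
  p <- (1 + cnt) / (1 + n_permutations)
  inact <- !coact$active
  p[inact, ] <- 1; p[, inact] <- 1
  diag(p) <- NA_real_
  if (adjust == "BH") {
    ut <- upper.tri(p)
    p_adj <- p
    p_adj[ut] <- stats::p.adjust(p[ut], method = "BH")
    p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
    p_use <- p_adj
  } else {
    p_use <- p
  }
  adjacency <- !is.na(p_use) & p_use <= alpha
  diag(adjacency) <- FALSE
  dimnames(p) <- dimnames(adjacency) <- dimnames(coact$C)
  coact$p_values <- p
  coact$adjacency <- adjacency
  coact$alpha <- alpha
  coact$n_permutations <- as.integer(n_permutations)
  coact$scheme <- scheme
  coact
}

#' Classify hub cells from significant links
#'
#' Hubs are the superconnected minority: cells holding 60-100% of the
#' correlated links. Each cell's significant-link count is expressed as a
#' percentage of a normalizer: by default the maximum per-cell link count
#' observed in the same islet (`"max_observed"`), alternatively the number
#' of possible partners (`"n_minus_1"`). A cell is a hub when its link
#' percentage reaches `threshold_percent` (ties included) and it has at
#' least one link. `hub_fraction` is taken over active cells only.
#'
#' @param coact a `coactivity` object with `adjacency` computed.
#' @param threshold_percent hub threshold, default 60.
#' @param normalization `"max_observed"` or `"n_minus_1"`.
#' @return An object of class `hub_classification`: data.frame with
#'   `cell_id`, `link_count`, `link_percent`, `is_hub`, plus attributes
#'   `hub_fraction`, `threshold_percent`, `normalization`.
#' @examples
#' # link counts [9, 9, 1, 1, 1, 0] -> percentages [100, 100, 11.1, ...]
#' @export
classify_hubs <- function(coact, threshold_percent = 60,
                          normalization = c("max_observed", "n_minus_1")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(coact, "coactivity"))
  if (is.null(coact$adjacency)) {
    stop("run permutation_significance() first", call. = FALSE)
  }
  link_count <- rowSums(coact$adjacency)
  denom <- switch(normalization,
                  max_observed = max(link_count),
                  n_minus_1 = length(link_count) - 1)
  link_percent <- if (denom > 0) 100 * link_count / denom else
    rep(0, length(link_count))
  is_hub <- link_percent >= threshold_percent & link_count > 0
  n_active <- sum(coact$active)
  out <- data.frame(cell_id = coact$cell_ids, link_count = link_count,
                    link_percent = link_percent, is_hub = is_hub,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "hub_fraction") <- if (n_active > 0) sum(is_hub) / n_active else 0
  attr(out, "threshold_percent") <- threshold_percent
  attr(out, "normalization") <- normalization
  class(out) <- c("hub_classification", "data.frame")
  out
}

#' @export
print.hub_classification <- function(x, ...) {
  cat(sprintf("hub_classification: %d hubs / %d cells (hub fraction %.3f, threshold %g%%)\n",
              sum(x$is_hub), nrow(x), attr(x, "hub_fraction"),
              attr(x, "threshold_percent")))
  invisible(x)
}

#' Summarize islet connectivity
#'
#' Connectivity indexes coordinated population activity: the percentage of
#' active-cell pairs whose co-activity is significant versus the permutation
#' null, together with the mean significant co-activity coefficient and the
#' per-cell link-count distribution.
#'
#' @param coact a `coactivity` object with `adjacency` computed.
#' @return A list of class `connectivity_summary`: `percent_connected_pairs`,
#'   `mean_significant_C`, `n_active_cells`, `n_significant_pairs`,
#'   `link_histogram` (table of per-cell link counts).
#' @export
connectivity_summary <- function(coact) {
  stopifnot(inherits(coact, "coactivity"))
  if (is.null(coact$adjacency)) {
    stop("run permutation_significance() first", call. = FALSE)
  }
  act <- which(coact$active)
  n_act <- length(act)
  n_pairs <- n_act * (n_act - 1) / 2
  sig <- coact$adjacency & upper.tri(coact$adjacency)
  A_act <- coact$adjacency[act, act, drop = FALSE]
  n_sig <- sum(A_act[upper.tri(A_act)])
  pct <- if (n_pairs > 0) 100 * n_sig / n_pairs else 0
  mean_sig_C <- if (any(sig)) mean(coact$C[sig]) else NA_real_
  structure(list(percent_connected_pairs = pct,
                 mean_significant_C = mean_sig_C,
                 n_active_cells = n_act,
                 n_significant_pairs = sum(sig),
                 link_histogram = table(rowSums(coact$adjacency))),
            class = "connectivity_summary")
}

#' @export
print.connectivity_summary <- function(x, ...) {
  cat(sprintf("connectivity: %.1f%% of active-cell pairs significant (%d pairs, %d active cells)\n",
              x$percent_connected_pairs, x$n_significant_pairs,
              x$n_active_cells))
  if (!is.na(x$mean_significant_C)) {
    cat(sprintf("mean significant C = %.3f\n", x$mean_significant_C))
  }
  invisible(x)
}

#' @export
summary.coactivity <- function(object, ...) connectivity_summary(object)

#' Build a functional connectivity map
#'
#' Combines the significant-link structure with the cells' Euclidean ROI
#' coordinates into a node table and edge list suitable for plotting hubs
#' on the imaged field of view.
#'
#' @param coact a `coactivity` object with `adjacency` computed.
#' @param hubs a [classify_hubs()] result.
#' @param coords data.frame with `x`, `y` per cell.
#' @return An object of class `connectivity_map`: list with `nodes`
#'   (`cell_id`, `x`, `y`, `link_count`, `link_percent`, `is_hub`) and
#'   `edges` (`cell_a`, `cell_b`, `C`, `p`).
#' @export
build_connectivity_map <- function(coact, hubs, coords) {
  stopifnot(inherits(coact, "coactivity"), inherits(hubs, "hub_classification"))
  if (is.null(coact$adjacency)) {
    stop("run permutation_significance() first", call. = FALSE)
  }
  n <- length(coact$cell_ids)
  if (is.null(coords) || nrow(coords) != n ||
      !all(c("x", "y") %in% names(coords))) {
    stop("coordinates missing or incomplete for cells: need (x, y) for all",
         call. = FALSE)
  }
  if (any(!is.finite(coords$x)) || any(!is.finite(coords$y))) {
    bad <- which(!is.finite(coords$x) | !is.finite(coords$y))
    stop(sprintf("missing coordinates for cells: %s",
                 paste(coact$cell_ids[bad], collapse = ", ")), call. = FALSE)
  }
  nodes <- data.frame(cell_id = coact$cell_ids, x = coords$x, y = coords$y,
                      link_count = hubs$link_count,
                      link_percent = hubs$link_percent,
                      is_hub = hubs$is_hub, stringsAsFactors = FALSE)
  idx <- which(upper.tri(coact$adjacency) & coact$adjacency, arr.ind = TRUE)
  edges <- data.frame(cell_a = coact$cell_ids[idx[, 1]],
                      cell_b = coact$cell_ids[idx[, 2]],
                      C = coact$C[idx], p = coact$p_values[idx],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("connectivity_map: %d nodes (%d hubs), %d edges\n",
              nrow(x$nodes), sum(x$nodes$is_hub), nrow(x$edges)))
  invisible(x)
}

#' Plot a functional connectivity map
#'
#' Draws significant links as line segments between ROI coordinates, with
#' hub cells highlighted in red and sized by their link percentage.
#'
#' @param x a `connectivity_map`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.connectivity_map <- function(x, ...) {
  nd <- x$nodes
  graphics::plot(nd$x, nd$y, type = "n", asp = 1, xlab = "x", ylab = "y",
                 main = "functional connectivity map", ...)
  if (nrow(x$edges)) {
    a <- match(x$edges$cell_a, nd$cell_id)
    b <- match(x$edges$cell_b, nd$cell_id)
    graphics::segments(nd$x[a], nd$y[a], nd$x[b], nd$y[b],
                       col = grDevices::adjustcolor("grey40", 0.5))
  }
  cex <- 0.8 + 1.2 * nd$link_percent / 100
  graphics::points(nd$x, nd$y, pch = 21, cex = cex,
                   bg = ifelse(nd$is_hub, "red", "steelblue"))
  invisible(x)
}
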
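## Empirical mode decomposition (Hilbert-Huang sifting).
##
## Implemented here with the standard ingredients: cubic-spline upper/lower
## envelopes through local extrema, mirror extension of extrema at the record
## boundaries, a Cauchy-type standard-deviation stopping criterion for the
## sifting loop, and extraction repeated on the remainder until the residue
## is monotone (or the IMF cap is reached).

## Indices of strict local maxima/minima; plateaus contribute their midpoint.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  ## collapse exact plateaus so runs of equal values yield one extremum
  s <- sign(d)
  idx_max <- integer(0); idx_min <- integer(0)
  last_s <- 0; last_i <- 1L
  for (i in seq_along(s)) {
    if (s[i] == 0) next
    if (last_s > 0 && s[i] < 0) idx_max <- c(idx_max, (last_i + i + 1L) %/% 2L)
    if (last_s < 0 && s[i] > 0) idx_min <- c(idx_min, (last_i + i + 1L) %/% 2L)
    last_s <- s[i]; last_i <- i + 1L
  }
  list(max = idx_max, min = idx_min)
}

## Spline envelope through (idx, x[idx]) with mirror extension of up to
## `n_mirror` extrema beyond each boundary, evaluated on 1..n.
spline_envelope <- function(x, idx, n, n_mirror = 2) {
  xi <- as.numeric(idx)
  yi <- x[idx]
  m <- length(xi)
  take <- seq_len(min(n_mirror, m))
  left_x <- 2 - xi[take]           # reflect about t = 1
  left_y <- yi[take]
  right_x <- 2 * n - xi[m + 1 - take]  # reflect about t = n
  right_y <- yi[m + 1 - take]
  ord <- order(c(left_x, xi, right_x))
  px <- c(left_x, xi, right_x)[ord]
  py <- c(left_y, yi, right_y)[ord]
  keep <- !duplicated(px)
  stats::spline(px[keep], py[keep], xout = seq_len(n), method = "fmm")$y
}

is_monotone <- function(x) {
  d <- diff(x)
  all(d >= 0) || all(d <= 0)
}

#' Empirical mode decomposition of a single trace
#'
#' Decomposes a series into intrinsic mode functions (IMFs) ordered from the
#' highest to the lowest frequency, plus a residue, by iterated sifting:
#' the mean of the cubic-spline envelopes through the local maxima and minima
#' is subtracted until the Cauchy-type criterion
#' \eqn{\sum (h_{k-1}-h_k)^2 / \sum h_{k-1}^2 < sd\_tol} is met, then the IMF
#' is removed and the procedure repeats on the remainder. Extraction stops
#' when the remainder is monotone, has fewer than two maxima or minima, or
#' `max_imfs` is reached. The components always reconstruct the input:
#' `rowSums(cbind(imfs, residue)) == x` to numerical precision, since each
#' IMF is an exact difference of intermediate remainders.
#'
#' @param x numeric vector, length >= 8, all finite.
#' @param max_imfs maximum number of IMFs to extract.
#' @param max_sifts cap on sifting iterations per IMF.
#' @param sd_tol Cauchy stopping tolerance for the sifting loop.
#' @return An object of class `emd_decomposition`: list with `imfs` (matrix,
#'   one column per IMF, possibly zero columns), `residue` (numeric vector)
#'   and `input` (the original series).
#' @examples
#' t <- seq(0, 10, by = 0.05)
#' d <- emd_decompose(sin(2 * pi * t) + 0.2 * t)
#' max(abs(rowSums(cbind(d$imfs, d$residue)) - d$input))
#' @export
emd_decompose <- function(x, max_imfs = 12, max_sifts = 50, sd_tol = 0.2) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("emd_decompose requires at least 8 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("emd_decompose requires finite input", call. = FALSE)

  imfs <- matrix(numeric(0), nrow = n, ncol = 0)
  resid <- x
  for (k in seq_len(max_imfs)) {
    ex <- local_extrema(resid)
    if (length(ex$max) < 2 || length(ex$min) < 2 || is_monotone(resid)) break
    h <- resid
    for (s in seq_len(max_sifts)) {
      exh <- local_extrema(h)
      if (length(exh$max) < 2 || length(exh$min) < 2) break
      upper <- spline_envelope(h, exh$max, n)
      lower <- spline_envelope(h, exh$min, n)
      m <- (upper + lower) / 2
      h_new <- h - m
      sd_k <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (sd_k < sd_tol) break
    }
    imfs <- cbind(imfs, h)
    resid <- resid - h
  }
  colnames(imfs) <- if (ncol(imfs)) paste0("imf", seq_len(ncol(imfs))) else NULL
  structure(list(imfs = imfs, residue = resid, input = x),
            class = "emd_decomposition")
}

#' @export
print.emd_decomposition <- function(x, ...) {
  cat(sprintf("emd_decomposition: %d IMFs + residue over %d samples\n",
              ncol(x$imfs), length(x$input)))
  invisible(x)
}

## Mean period (in frames) of a component, from its zero-crossing count.
mean_period_frames <- function(v) {
  v <- v - mean(v)
  zc <- sum(diff(sign(v + (v == 0) * .Machine$double.eps)) != 0)
  if (zc < 1) return(Inf)
  2 * length(v) / zc
}
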
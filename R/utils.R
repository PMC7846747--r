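# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

next_pow2 <- function(n) 2^ceiling(log2(n))

## Run a block with a deterministic RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

## Lengths and start indices of runs of 1s in a 0/1 vector.
on_runs <- function(x) {
  r <- rle(as.integer(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  list(start = starts[keep], length = r$lengths[keep])
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf, integer = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x)) {
    stop_config(field, "must be a single finite number")
  }
  if (x < lower || x > upper) {
    stop_config(field, sprintf("must be in [%s, %s]", lower, upper))
  }
  if (integer && x != round(x)) stop_config(field, "must be an integer")
  x
}

signif9 <- function(x) signif(x, 9)
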
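# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop_invalid("`%s` must be a finite number in [%g, %g]", name, lo, hi)
  invisible(x)
}

assert_fraction <- function(x, name) assert_scalar_num(x, name, 0, 1)

# centered moving average over w points (MATLAB movmean convention:
# ceiling((w-1)/2) points back, floor((w-1)/2) forward, windows clipped
# at the edges); w > n collapses to the global mean
moving_average <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 0L) return(x)
  if (w > n) return(rep(mean(x), n))
  back <- ceiling((w - 1) / 2)
  fwd <- floor((w - 1) / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - back, 1L)
  hi <- pmin(i + fwd, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
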
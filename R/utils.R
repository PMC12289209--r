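# Internal numeric helpers shared across modules.

#' Centered moving average with shrinking edge windows
#'
#' Smooths a series with a boxcar of `window` samples centered on each point.
#' At the edges the window shrinks to the available samples, so constant
#' inputs are reproduced exactly and no phase lag is introduced.
#'
#' @param x numeric vector.
#' @param window window size in samples (>= 1). Even windows place the extra
#'   sample on the left of the center, matching a centered 30-sample smoother.
#' @return numeric vector of `length(x)`.
#' @export
moving_average <- function(x, window = 30L) {
  if (length(x) == 0L) stop("empty input")
  if (!all(is.finite(x))) stop("input must be finite")
  w <- as.integer(window)
  if (is.na(w) || w < 1L) stop("window must be >= 1")
  n <- length(x)
  kl <- w %/% 2L
  kr <- w - 1L - kl
  cs <- cumsum(x)
  i <- seq_len(n)
  hi <- pmin(i + kr, n)
  lo <- pmax(i - kl, 1L)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
}

# Hann taper of length n (periodic-symmetric form used for spectral windows).
hann_taper <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1L)) / (n - 1L)))
}

# Run code with a local RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be positive", name))
  invisible(x)
}
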
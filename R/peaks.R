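# Topographic peak analysis: local maxima, prominence, width at
# half-prominence. These primitives back the trainable fin-stroke detector.

# Indices of strict local maxima; flat-topped plateaus contribute their
# midpoint. Endpoints are never maxima.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  k <- length(r$values)
  i <- 1L
  while (i <= k) {
    if (r$values[i] == 1) {
      # run of rises ending at sample ends[i] + 1
      j <- i + 1L
      flat <- 0L
      if (j <= k && r$values[j] == 0) {
        flat <- r$lengths[j]
        j <- j + 1L
      }
      if (j <= k && r$values[j] == -1) {
        top_start <- ends[i] + 1L
        out <- c(out, top_start + flat %/% 2L)
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  out
}

# Nearest index left (dir = -1) or right (dir = +1) of p with x > x[p];
# 0 when none exists before the signal edge. Scans outward in growing
# blocks so dense low peaks stay cheap.
nearest_higher <- function(x, p, dir) {
  n <- length(x)
  v <- x[p]
  step <- 64L
  if (dir < 0) {
    hi <- p - 1L
    while (hi >= 1L) {
      lo <- max(1L, hi - step + 1L)
      w <- which(x[lo:hi] > v)
      if (length(w)) return(lo + w[length(w)] - 1L)
      hi <- lo - 1L
      step <- step * 4L
    }
  } else {
    lo <- p + 1L
    while (lo <= n) {
      hi <- min(n, lo + step - 1L)
      w <- which(x[lo:hi] > v)
      if (length(w)) return(lo + w[1L] - 1L)
      lo <- hi + 1L
      step <- step * 4L
    }
  }
  0L
}

# Interpolated crossing of `level` walking away from peak p within
# (bound, p] / [p, bound); returns fractional index, clipped to the bound
# when the signal never drops below the level on that side.
cross_level <- function(x, p, level, bound, dir) {
  if (dir < 0) {
    k <- p - 1L
    while (k >= bound) {
      if (x[k] < level) {
        return(k + (level - x[k]) / (x[k + 1L] - x[k]))
      }
      k <- k - 1L
    }
    as.numeric(bound)
  } else {
    k <- p + 1L
    while (k <= bound) {
      if (x[k] < level) {
        return(k - (level - x[k]) / (x[k - 1L] - x[k]))
      }
      k <- k + 1L
    }
    as.numeric(bound)
  }
}

#' Enumerate peak candidates with prominence and width
#'
#' Finds every local maximum of a conditioned fin signal and annotates it
#' with its topographic prominence and its width measured at half-prominence
#' height (peak height minus half the prominence). The candidate table is
#' parameter-free: a [peak_params()] setting is just a filter on it, which is
#' what makes grid-search training of the detector cheap.
#'
#' @param signal a `conditioned_signal` (see [condition_signal()]), or a
#'   numeric vector with `fs` giving its sampling rate.
#' @param fs sampling rate in Hz, taken from the signal when available.
#' @return data frame with columns `index`, `time_s`, `value`, `prominence`,
#'   `width_s`.
#' @export
peak_candidates <- function(signal, fs = NULL) {
  if (inherits(signal, "conditioned_signal")) {
    x <- signal$value
    fs <- attr(signal, "fs")
    t0 <- signal$time_s[1L]
  } else {
    x <- as.numeric(signal)
    fs <- fs %||% 100
    t0 <- 0
  }
  n <- length(x)
  pk <- local_maxima(x)
  m <- length(pk)
  prom <- numeric(m)
  width <- numeric(m)
  for (j in seq_len(m)) {
    p <- pk[j]
    lh <- nearest_higher(x, p, -1L)
    rh <- nearest_higher(x, p, +1L)
    lb <- if (lh == 0L) 1L else lh
    rb <- if (rh == 0L) n else rh
    lmin <- if (lb <= p - 1L) min(x[lb:(p - 1L)]) else x[p]
    rmin <- if (p + 1L <= rb) min(x[(p + 1L):rb]) else x[p]
    prom[j] <- x[p] - max(lmin, rmin)
    level <- x[p] - prom[j] / 2
    li <- cross_level(x, p, level, lb, -1L)
    ri <- cross_level(x, p, level, rb, +1L)
    width[j] <- (ri - li) / fs
  }
  data.frame(
    index = pk,
    time_s = t0 + (pk - 1L) / fs,
    value = x[pk],
    prominence = prom,
    width_s = width
  )
}
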
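# Fin-stroke detection: magnetometer conditioning, parametrized peak
# detection, grid-search training against annotated segments, and removal
# of orientation-change artefacts by the inter-fin-interval rule.

#' Condition the magnetometer signal for fin-stroke detection
#'
#' Sums the absolute values of the three magnetometer axes and smooths the
#' result with a centered 30-sample moving average. The summed magnitude
#' makes the fin-magnet modulation orientation-independent; the smoother
#' suppresses sensor noise without shifting peak times.
#'
#' @param x a `tag_recording`, or a 3-column matrix/data frame of
#'   magnetometer axes sampled at `fs`.
#' @param window moving-average window in samples.
#' @param fs sampling rate in Hz (taken from a `tag_recording`).
#' @param time optional time vector (s) when `x` is a bare matrix.
#' @return data frame of class `conditioned_signal` with columns `time_s`
#'   and `value` (non-negative), attribute `fs`.
#' @export
condition_signal <- function(x, window = 30L, fs = 100, time = NULL) {
  if (inherits(x, "tag_recording")) {
    m <- as.matrix(x$fast[, c("mx", "my", "mz")])
    time <- x$fast$time_s
    fs <- x$fs
  } else {
    m <- as.matrix(x)
    if (ncol(m) != 3L) stop("expected three magnetometer axes")
  }
  if (nrow(m) == 0L) stop("empty input")
  if (!all(is.finite(m))) stop("magnetometer input must be finite")
  v <- moving_average(rowSums(abs(m)), window)
  out <- data.frame(
    time_s = if (is.null(time)) (seq_len(nrow(m)) - 1L) / fs else time,
    value = v
  )
  class(out) <- c("conditioned_signal", "data.frame")
  attr(out, "fs") <- fs
  out
}

#' Peak-detector parameters
#'
#' The three tunable parameters of the fin-stroke peak detector: minimum
#' topographic prominence, and minimum/maximum peak width measured at
#' half-prominence height.
#'
#' @param min_prominence minimum peak prominence (conditioned-signal units).
#' @param min_width,max_width admissible width range at half-prominence (s).
#' @return list of class `peak_params`.
#' @export
peak_params <- function(min_prominence = 0.3, min_width = 0.15,
                        max_width = 1.5) {
  stopifnot_scalar(min_prominence, "min_prominence", positive = TRUE)
  stopifnot_scalar(min_width, "min_width", positive = TRUE)
  stopifnot_scalar(max_width, "max_width", positive = TRUE)
  if (min_width >= max_width) stop("min_width must be < max_width")
  structure(list(min_prominence = min_prominence, min_width = min_width,
                 max_width = max_width), class = "peak_params")
}

#' Detect fin strokes in a conditioned signal
#'
#' Returns every local maximum whose topographic prominence is at least
#' `min_prominence` and whose width at half-prominence lies in
#' `[min_width, max_width]`. On a clean fin sinusoid this yields exactly one
#' event per upstroke--downstroke cycle.
#'
#' @param signal a `conditioned_signal` (or numeric vector with `fs`).
#' @param params a [peak_params()] setting.
#' @param fs sampling rate when `signal` is a bare vector.
#' @return data frame of class `fin_events` with columns `time_s`,
#'   `prominence`, `width_s` (sorted by time) and attribute `params_used`.
#' @export
detect_peaks <- function(signal, params = peak_params(), fs = NULL) {
  if (!inherits(params, "peak_params")) params <- do.call(peak_params, params)
  cand <- peak_candidates(signal, fs = fs)
  filter_candidates(cand, params)
}

# Apply a peak_params filter to a candidate table.
filter_candidates <- function(cand, params) {
  keep <- cand$prominence >= params$min_prominence &
    cand$width_s >= params$min_width &
    cand$width_s <= params$max_width
  out <- cand[keep, c("time_s", "prominence", "width_s")]
  rownames(out) <- NULL
  class(out) <- c("fin_events", "data.frame")
  attr(out, "params_used") <- params
  out
}

#' Remove doubly-isolated peaks (orientation artefacts)
#'
#' Removes every detected event whose inter-fin interval exceeds `max_gap`
#' seconds both before and after the event. Isolated crests cannot be part
#' of a fin-stroke sequence and are attributed to slow orientation changes.
#' The recording edges count as an infinite gap on the open side, so a lone
#' first or last event is removed when its one-sided neighbour gap also
#' exceeds `max_gap`. The filter is idempotent.
#'
#' @param events a `fin_events` data frame (sorted by time).
#' @param max_gap isolation threshold in seconds.
#' @return filtered `fin_events`, with attribute `removed_times` holding the
#'   event times that were dropped.
#' @export
filter_isolated_peaks <- function(events, max_gap = 4) {
  t <- events$time_s
  if (is.unsorted(t)) stop("events must be sorted by time")
  if (length(t) == 0L) return(events)
  gap_prev <- c(Inf, diff(t))
  gap_next <- c(diff(t), Inf)
  keep <- !(gap_prev > max_gap & gap_next > max_gap)
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(events)
  attr(out, "params_used") <- attr(events, "params_used")
  attr(out, "removed_times") <- t[!keep]
  out
}

#' One-to-one event matching by nearest time
#'
#' Greedily pairs detected events with reference events, closest pairs
#' first, each event used at most once, pairs admissible within `tol`.
#'
#' @param detected,reference sorted numeric vectors of event times (s).
#' @param tol matching tolerance (s).
#' @return list with `n_matched`, `recall`, `precision`.
#' @export
match_events <- function(detected, reference, tol = 0.25) {
  nd <- length(detected); nr <- length(reference)
  if (nd == 0L || nr == 0L) {
    return(list(n_matched = 0L,
                recall = if (nr == 0L) 1 else 0,
                precision = if (nd == 0L) 1 else 0))
  }
  # candidate pairs: detections within tol of each reference
  lo <- findInterval(reference - tol, detected) + 1L
  hi <- findInterval(reference + tol, detected)
  nn <- hi - lo + 1L
  if (all(nn <= 1L)) {
    # fast path: at most one candidate per reference
    ok <- nn == 1L
    idx <- lo[ok]
    if (!any(duplicated(idx))) {
      n <- sum(ok)
      return(list(n_matched = n, recall = n / nr, precision = n / nd))
    }
  }
  ri <- rep.int(seq_len(nr), pmax(nn, 0L))
  di <- unlist(lapply(seq_len(nr), function(i) {
    if (nn[i] < 1L) integer(0) else lo[i]:hi[i]
  }), use.names = FALSE)
  if (length(di) == 0L) {
    return(list(n_matched = 0L, recall = 0, precision = 0))
  }
  d <- abs(detected[di] - reference[ri])
  o <- order(d)
  used_d <- logical(nd); used_r <- logical(nr)
  n <- 0L
  for (k in o) {
    if (!used_d[di[k]] && !used_r[ri[k]]) {
      used_d[di[k]] <- TRUE
      used_r[ri[k]] <- TRUE
      n <- n + 1L
    }
  }
  list(n_matched = n, recall = n / nr, precision = n / nd)
}

#' Parameter grid for detector training
#'
#' Cartesian grid over the three detector parameters. Defaults use
#' log-spaced prominences and linear-spaced widths, and include the package
#' default [peak_params()] values on each axis.
#'
#' @param min_prominence,min_width,max_width numeric axis values.
#' @return data frame of class `param_grid` with one row per combination
#'   and attribute `n_combinations` (the product of the axis lengths).
#' @export
param_grid <- function(min_prominence = sort(unique(c(0.3,
                         exp(seq(log(0.05), log(2.5), length.out = 24))))),
                       min_width = sort(unique(c(0.15,
                         seq(0.02, 0.5, length.out = 15)))),
                       max_width = sort(unique(c(1.5,
                         seq(0.6, 2.0, length.out = 12))))) {
  g <- expand.grid(min_prominence = min_prominence, min_width = min_width,
                   max_width = max_width, KEEP.OUT.ATTRS = FALSE)
  g <- g[g$min_width < g$max_width, , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("param_grid", "data.frame")
  attr(g, "n_combinations") <-
    length(min_prominence) * length(min_width) * length(max_width)
  g
}

#' Train the peak detector against annotated segments
#'
#' Reproduces the grid-search training procedure: for each manually
#' annotated segment, every grid combination is applied and the combinations
#' that mark 100% of the annotated fin crests (each crest matched one-to-one
#' by a detection within `tolerance`) are indexed as successful. The
#' successful settings pooled across segments are averaged field-wise to
#' give the returned setting, whose per-segment recall and precision are
#' reported. False-positive detections do not disqualify a combination
#' unless `require_no_extra = TRUE`; precision is always reported so users
#' can tighten the grid.
#'
#' @param signal a `conditioned_signal` covering all segments.
#' @param annotations list of annotated segments, each a list with `start`,
#'   `end` (s) and `times` (annotated crest times, s).
#' @param grid a [param_grid()].
#' @param tolerance matching tolerance between a detection and an annotated
#'   crest (s).
#' @param require_no_extra if TRUE, combinations producing more detections
#'   than annotations in a segment are rejected.
#' @return list of class `fin_optim`: `params` (the averaged
#'   [peak_params()]), `successes` (data frame of all successful
#'   segment/combination pairs with their precision), and `per_segment`
#'   (recall/precision of the averaged setting on each training segment).
#' @export
optimize_peak_params <- function(signal, annotations, grid = param_grid(),
                                 tolerance = 0.25, require_no_extra = FALSE) {
  if (length(annotations) < 1L) stop("need at least one annotated segment")
  if (nrow(grid) < 1L) stop("grid is empty")
  cand_all <- peak_candidates(signal)
  seg_cand <- lapply(annotations, function(a) {
    cand_all[cand_all$time_s >= a$start & cand_all$time_s <= a$end, ,
             drop = FALSE]
  })
  succ <- vector("list", length(annotations))
  best_recall <- numeric(length(annotations))
  for (s in seq_along(annotations)) {
    ann <- sort(annotations[[s]]$times)
    cand <- seg_cand[[s]]
    prom <- cand$prominence
    wid <- cand$width_s
    tms <- cand$time_s
    rows <- integer(0)
    prec <- numeric(0)
    for (g in seq_len(nrow(grid))) {
      sel <- tms[prom >= grid$min_prominence[g] &
                   wid >= grid$min_width[g] & wid <= grid$max_width[g]]
      if (length(sel) < length(ann)) {
        best_recall[s] <- max(best_recall[s],
                              min(length(sel) / length(ann), 1))
        next
      }
      m <- match_events(sel, ann, tol = tolerance)
      best_recall[s] <- max(best_recall[s], m$recall)
      if (m$recall == 1 &&
          (!require_no_extra || length(sel) == length(ann))) {
        rows <- c(rows, g)
        prec <- c(prec, m$precision)
      }
    }
    if (length(rows)) {
      succ[[s]] <- data.frame(segment = s, grid_row = rows,
                              grid[rows, , drop = FALSE],
                              precision = prec, row.names = NULL)
    }
  }
  successes <- do.call(rbind, succ[!vapply(succ, is.null, logical(1))])
  if (is.null(successes) || nrow(successes) == 0L) {
    stop(sprintf(
      "no parameter combination marked 100%% of annotated crests on any segment (best recall per segment: %s)",
      paste(sprintf("%.3f", best_recall), collapse = ", ")))
  }
  empty <- setdiff(seq_along(annotations), unique(successes$segment))
  if (length(empty)) {
    warning(sprintf(
      "no successful combination on segment(s) %s (best recall %s); averaging over the remaining segments",
      paste(empty, collapse = ", "),
      paste(sprintf("%.3f", best_recall[empty]), collapse = ", ")))
  }
  avg <- peak_params(
    min_prominence = mean(successes$min_prominence),
    min_width = mean(successes$min_width),
    max_width = mean(successes$max_width)
  )
  per_segment <- do.call(rbind, lapply(seq_along(annotations), function(s) {
    ann <- sort(annotations[[s]]$times)
    ev <- filter_candidates(seg_cand[[s]], avg)
    m <- match_events(ev$time_s, ann, tol = tolerance)
    data.frame(segment = s, n_annotated = length(ann),
               n_detected = nrow(ev), recall = m$recall,
               precision = m$precision)
  }))
  structure(list(params = avg, successes = successes,
                 per_segment = per_segment, tolerance = tolerance),
            class = "fin_optim")
}

#' @export
print.fin_optim <- function(x, ...) {
  cat(sprintf(
    "<fin_optim> %d successful setting(s); averaged: prominence >= %.3f, width %.3f-%.3f s\n",
    nrow(x$successes), x$params$min_prominence, x$params$min_width,
    x$params$max_width))
  print(x$per_segment, row.names = FALSE)
  invisible(x)
}
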
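# Gait classification: 1 s activity windows, glide extraction, 5 s
# Hann/zero-padded FFT dominant frequencies, bimodal frequency split, and
# time budgets.

#' Spectral settings for dominant-frequency analysis
#'
#' @param window_s FFT window length (s).
#' @param zero_pad number of zeros appended to each tapered window; with the
#'   defaults the frequency resolution is `fs / (window_s * fs + zero_pad)`,
#'   about 0.0095 Hz.
#' @param fs sampling rate (Hz).
#' @return list of class `spectral_config`.
#' @export
spectral_config <- function(window_s = 5, zero_pad = 10000L, fs = 100) {
  stopifnot_scalar(window_s, "window_s", positive = TRUE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (zero_pad < 0) stop("zero_pad must be >= 0")
  structure(list(window_s = window_s, zero_pad = as.integer(zero_pad),
                 fs = fs,
                 resolution_hz = fs / (window_s * fs + zero_pad)),
            class = "spectral_config")
}

#' Extract dynamic surge acceleration
#'
#' Separates the dynamic (movement) component of the surge-axis acceleration
#' from the gravitational/postural component by subtracting a centered
#' moving average. The default 0.5 s separation scale passes fin- and
#' jet-frequency movements while removing the quasi-static gravity
#' projection, so a stationary animal yields (near-)zero dynamic surge.
#'
#' @param x a `tag_recording`, or a numeric surge-axis series (g).
#' @param fs sampling rate (Hz) when `x` is a bare vector.
#' @param window_s postural/dynamic separation scale (s).
#' @return numeric vector of dynamic surge acceleration (g).
#' @export
extract_dynamic_surge <- function(x, fs = 100, window_s = 0.5) {
  if (inherits(x, "tag_recording")) {
    fs <- x$fs
    x <- x$fast$ax_g
  }
  if (length(x) == 0L) stop("empty input")
  if (!all(is.finite(x))) stop("input must be finite")
  x - moving_average(x, round(window_s * fs))
}

#' Label 1 s windows active or inactive
#'
#' A window is `active` when it contains at least one detected fin event or
#' its maximum absolute dynamic surge exceeds `threshold`; otherwise it is
#' `inactive`.
#'
#' @param fin_events a `fin_events` data frame or numeric vector of event
#'   times (s).
#' @param surge dynamic surge series (g) from [extract_dynamic_surge()].
#' @param fs sampling rate of `surge` (Hz).
#' @param threshold surge activity threshold (g).
#' @return data frame with columns `start_s`, `has_fin_event`, `max_surge`,
#'   `label`, one row per whole 1 s window.
#' @export
label_windows <- function(fin_events, surge, fs = 100, threshold = 0.10) {
  ev <- if (is.data.frame(fin_events)) fin_events$time_s else as.numeric(fin_events)
  n_win <- floor(length(surge) / fs)
  if (n_win < 1L) stop("surge series shorter than one window")
  idx <- seq_len(n_win * fs)
  win <- (idx - 1L) %/% as.integer(fs)
  max_surge <- as.numeric(tapply(abs(surge[idx]), win, max))
  counts <- tabulate(floor(ev) + 1L, nbins = n_win)
  has_fin <- counts > 0L
  data.frame(
    start_s = as.numeric(0:(n_win - 1L)),
    has_fin_event = has_fin,
    max_surge = max_surge,
    label = ifelse(has_fin | max_surge > threshold, "active", "inactive")
  )
}

#' Segment labelled windows into glides and active runs
#'
#' Maximal runs of inactive windows lasting at least `min_glide` seconds
#' become `glide` segments. Shorter inactive runs flanked by activity are
#' folded into the surrounding active run -- inactivity only counts as a
#' behavioural state when it persists for `min_glide` consecutive seconds --
#' while short inactive runs at the recording edges, which have no
#' surrounding activity, are `unclassified`. Maximal active runs are
#' returned as `active` segments for spectral classification.
#'
#' @param windows output of [label_windows()].
#' @param min_glide minimum glide duration (s).
#' @param merge_short_inactive fold sub-`min_glide` inactive runs into the
#'   surrounding active run (default) instead of leaving them unclassified.
#' @return data frame with columns `start_s`, `end_s`, `state` (one of
#'   `active`, `glide`, `unclassified`) covering the windows exactly once.
#' @export
segment_states <- function(windows, min_glide = 5,
                           merge_short_inactive = TRUE) {
  lab <- windows$label
  n <- length(lab)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  kind <- character(length(r$values))
  for (i in seq_along(r$values)) {
    if (r$values[i] == "active") {
      kind[i] <- "active"
    } else if (r$lengths[i] >= min_glide) {
      kind[i] <- "glide"
    } else if (merge_short_inactive && i > 1L && i < length(r$values) &&
               r$values[i - 1L] == "active" && r$values[i + 1L] == "active") {
      kind[i] <- "active"
    } else {
      kind[i] <- "unclassified"
    }
  }
  # merge adjacent runs of the same effective kind
  keep <- c(TRUE, kind[-1L] != kind[-length(kind)])
  seg_start <- starts[keep]
  seg_kind <- kind[keep]
  seg_end <- c(seg_start[-1L] - 1L, n)
  data.frame(
    start_s = windows$start_s[seg_start],
    end_s = windows$start_s[seg_end] + 1,
    state = seg_kind
  )
}

#' Dominant frequency of a tapered, zero-padded FFT window
#'
#' Removes the mean, applies a Hann taper, zero pads, and returns the
#' frequency of the maximum-magnitude non-zero-frequency bin.
#'
#' @param x numeric signal segment (one analysis window).
#' @param cfg a [spectral_config()].
#' @return dominant frequency (Hz).
#' @export
dominant_frequency <- function(x, cfg = spectral_config()) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("segment too short")
  x <- x - mean(x)
  if (max(abs(x)) < 1e-12) stop("constant segment: dominant frequency undefined")
  xt <- x * hann_taper(length(x))
  n <- length(x) + cfg$zero_pad
  mag <- Mod(stats::fft(c(xt, numeric(cfg$zero_pad))))
  k <- 2:(floor(n / 2) + 1L)
  (k[which.max(mag[k])] - 1L) * cfg$fs / n
}

#' Locate the bimodal split frequency
#'
#' Per-animal dominant-frequency distributions are bimodal: a
#' higher-frequency metachronal-finning mode and a lower-frequency
#' jet/other mode. The split is the density minimum between the two largest
#' modes (separated by at least `min_sep`) of a Gaussian kernel density
#' estimate (Silverman bandwidth); when the density valley between them is
#' flat, the valley midpoint is used. When bimodality is not detected a
#' warning is raised and `fallback` returned.
#'
#' @param freqs dominant frequencies (Hz) of active 5 s windows.
#' @param fallback split frequency (Hz) used when the distribution is not
#'   bimodal.
#' @param min_n minimum number of windows required.
#' @param min_sep minimum separation (Hz) between the two modes; protects
#'   against reading sampling ripples within one tight frequency cluster as
#'   separate gait modes.
#' @param bw kernel bandwidth rule passed to [stats::density()].
#' @return split frequency (Hz).
#' @export
find_split_frequency <- function(freqs, fallback = 0.75, min_n = 50,
                                 min_sep = 0.2, bw = "nrd0") {
  freqs <- freqs[is.finite(freqs)]
  if (length(freqs) < min_n) {
    stop("need at least ", min_n, " dominant-frequency windows, got ",
         length(freqs))
  }
  d <- stats::density(freqs, bw = bw)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  m1 <- m2 <- NA_integer_
  if (length(is_max) >= 2L) {
    ord <- is_max[order(y[is_max], decreasing = TRUE)]
    m1 <- ord[1L]
    far <- ord[abs(d$x[ord] - d$x[m1]) >= min_sep]
    if (length(far)) m2 <- far[1L]
  }
  if (is.na(m1) || is.na(m2)) {
    warning("frequency distribution not bimodal; using fallback split of ",
            fallback, " Hz")
    return(fallback)
  }
  between <- min(m1, m2):max(m1, m2)
  ymin <- min(y[between])
  flat <- between[y[between] <= ymin + 1e-12 * max(y)]
  d$x[flat[ceiling(length(flat) / 2)]]
}

# Decision rule for one 5 s active window.
classify_window <- function(freq, max_surge, split, threshold = 0.10) {
  if (freq >= split) {
    list(state = "finning", jet_overlap = max_surge > threshold)
  } else if (max_surge > threshold) {
    list(state = "jet", jet_overlap = FALSE)
  } else {
    list(state = "other", jet_overlap = FALSE)
  }
}

#' Classify active runs into finning / jet / other 5 s windows
#'
#' Tiles each active run with non-overlapping windows of `cfg$window_s`
#' seconds from the start of the run; the trailing remainder shorter than a
#' window is `unclassified`. Each window is classified by its dominant fin
#' frequency and maximum absolute dynamic surge: at or above the split
#' frequency the window is `finning` (with `jet_overlap` flagged when the
#' surge also exceeds the threshold); below the split it is `jet` when the
#' surge exceeds the threshold and `other` when it does not.
#'
#' @param segments output of [segment_states()].
#' @param fin_signal the `conditioned_signal` for the whole recording.
#' @param surge dynamic surge series (g), same sampling rate.
#' @param split split frequency (Hz) from [find_split_frequency()].
#' @param threshold surge threshold (g).
#' @param cfg a [spectral_config()].
#' @return data frame with columns `start_s`, `end_s`, `state`,
#'   `dominant_freq`, `max_surge`, `jet_overlap`.
#' @export
classify_active_windows <- function(segments, fin_signal, surge, split,
                                    threshold = 0.10,
                                    cfg = spectral_config()) {
  stopifnot_scalar(split, "split", positive = TRUE)
  fs <- attr(fin_signal, "fs") %||% cfg$fs
  wlen <- cfg$window_s
  out <- list()
  for (i in seq_len(nrow(segments))) {
    st <- segments$state[i]
    a <- segments$start_s[i]; b <- segments$end_s[i]
    if (st != "active") {
      out[[length(out) + 1L]] <- data.frame(
        start_s = a, end_s = b, state = st, dominant_freq = NA_real_,
        max_surge = NA_real_, jet_overlap = FALSE)
      next
    }
    nw <- floor((b - a) / wlen)
    if (nw >= 1L) {
      for (k in seq_len(nw)) {
        w0 <- a + (k - 1L) * wlen
        idx <- (round(w0 * fs) + 1L):(round((w0 + wlen) * fs))
        dfreq <- tryCatch(
          dominant_frequency(fin_signal$value[idx], cfg),
          error = function(e) NA_real_)
        msur <- max(abs(surge[idx]))
        if (is.na(dfreq)) {
          out[[length(out) + 1L]] <- data.frame(
            start_s = w0, end_s = w0 + wlen, state = "unclassified",
            dominant_freq = NA_real_, max_surge = msur, jet_overlap = FALSE)
        } else {
          cl <- classify_window(dfreq, msur, split, threshold)
          out[[length(out) + 1L]] <- data.frame(
            start_s = w0, end_s = w0 + wlen, state = cl$state,
            dominant_freq = dfreq, max_surge = msur,
            jet_overlap = cl$jet_overlap)
        }
      }
    }
    rem <- (b - a) - nw * wlen
    if (rem > 0) {
      out[[length(out) + 1L]] <- data.frame(
        start_s = a + nw * wlen, end_s = b, state = "unclassified",
        dominant_freq = NA_real_, max_surge = NA_real_, jet_overlap = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start_s), , drop = FALSE]
  # merge adjacent same-state windows into segments
  brk <- cumsum(c(TRUE, res$state[-1L] != res$state[-nrow(res)] |
                    res$start_s[-1L] != res$end_s[-nrow(res)]))
  merged <- do.call(rbind, lapply(split(res, brk), function(g) {
    data.frame(start_s = g$start_s[1L], end_s = g$end_s[nrow(g)],
               state = g$state[1L],
               dominant_freq = mean(g$dominant_freq),
               max_surge = if (all(is.na(g$max_surge))) NA_real_
                           else max(g$max_surge, na.rm = TRUE),
               jet_overlap = any(g$jet_overlap))
  }))
  merged <- merged[order(merged$start_s), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Run the full gait-classification chain on a recording
#'
#' Conditions the magnetometer, extracts dynamic surge, labels 1 s activity
#' windows from a detected fin-event train, extracts glides, computes
#' dominant frequencies of 5 s active windows, locates the bimodal split
#' (unless supplied), and classifies every active window.
#'
#' @param recording a `tag_recording`.
#' @param fin_events detected (and artefact-filtered) `fin_events`.
#' @param surge_threshold activity/jet surge threshold (g).
#' @param min_glide minimum glide duration (s).
#' @param split optional fixed split frequency (Hz); estimated from the
#'   recording when NULL.
#' @param cfg a [spectral_config()].
#' @param split_fallback fallback split frequency when bimodality is absent.
#' @return list of class `gait_classification`: `segments` (the final
#'   partition), `split_freq`, `window_freqs` (dominant frequencies of all
#'   active windows).
#' @export
classify_gaits <- function(recording, fin_events, surge_threshold = 0.10,
                           min_glide = 5, split = NULL,
                           cfg = spectral_config(), split_fallback = 0.75) {
  sig <- condition_signal(recording)
  surge <- extract_dynamic_surge(recording)
  win <- label_windows(fin_events, surge, fs = recording$fs,
                       threshold = surge_threshold)
  seg <- segment_states(win, min_glide = min_glide)
  # dominant frequencies of all active 5 s windows (for the split)
  fs <- recording$fs
  freqs <- numeric(0)
  for (i in which(seg$state == "active")) {
    a <- seg$start_s[i]; b <- seg$end_s[i]
    nw <- floor((b - a) / cfg$window_s)
    for (k in seq_len(nw)) {
      w0 <- a + (k - 1L) * cfg$window_s
      idx <- (round(w0 * fs) + 1L):(round((w0 + cfg$window_s) * fs))
      f <- tryCatch(dominant_frequency(sig$value[idx], cfg),
                    error = function(e) NA_real_)
      freqs <- c(freqs, f)
    }
  }
  if (is.null(split)) {
    split <- find_split_frequency(freqs[is.finite(freqs)],
                                  fallback = split_fallback)
  }
  segments <- classify_active_windows(seg, sig, surge, split,
                                      threshold = surge_threshold, cfg = cfg)
  structure(list(segments = segments, split_freq = split,
                 window_freqs = freqs),
            class = "gait_classification")
}

#' Per-state time budget and finning statistics
#'
#' @param segments classified segment table (must partition the recording:
#'   contiguous, non-overlapping).
#' @param fin_events `fin_events` or numeric event times, used for the mean
#'   fin rate within finning segments.
#' @return list of class `time_budget`: `fractions` (named, sums to 1),
#'   `mean_fin_rate` (fins s^-1 during finning), `glide_durations` (s),
#'   `total_s`.
#' @export
compute_time_budget <- function(segments, fin_events = numeric(0)) {
  seg <- segments[order(segments$start_s), , drop = FALSE]
  if (nrow(seg) > 1L &&
      any(seg$start_s[-1L] < seg$end_s[-nrow(seg)] - 1e-9)) {
    stop("segments overlap")
  }
  if (nrow(seg) > 1L &&
      any(abs(seg$start_s[-1L] - seg$end_s[-nrow(seg)]) > 1e-9)) {
    stop("segments do not partition the recording (gaps present)")
  }
  dur <- seg$end_s - seg$start_s
  total <- sum(dur)
  states <- c("finning", "jet", "other", "glide", "unclassified")
  frac <- vapply(states, function(s) sum(dur[seg$state == s]) / total,
                 numeric(1))
  ev <- if (is.data.frame(fin_events)) fin_events$time_s else as.numeric(fin_events)
  fin_idx <- seg$state == "finning"
  fin_time <- sum(dur[fin_idx])
  n_fin_ev <- sum(vapply(which(fin_idx), function(i) {
    sum(ev >= seg$start_s[i] & ev < seg$end_s[i])
  }, numeric(1)))
  structure(list(
    fractions = frac,
    mean_fin_rate = if (fin_time > 0) n_fin_ev / fin_time else NA_real_,
    glide_durations = dur[seg$state == "glide"],
    total_s = total
  ), class = "time_budget")
}

#' @export
print.time_budget <- function(x, ...) {
  cat(sprintf("<time_budget> %.0f s total\n", x$total_s))
  for (s in names(x$fractions)) {
    cat(sprintf("  %-12s %5.1f%%\n", s, 100 * x$fractions[[s]]))
  }
  cat(sprintf("  mean fin rate: %.2f fins/s; %d glides (median %.1f s)\n",
              x$mean_fin_rate, length(x$glide_durations),
              if (length(x$glide_durations)) stats::median(x$glide_durations)
              else NA_real_))
  invisible(x)
}
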
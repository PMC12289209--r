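# Synthetic tag-recording generator. Emulates the statistical structure the
# downstream analysis assumes -- sinusoidal magnetometer modulation during
# metachronal finning, low-frequency fin cycles with surge pulses during
# jets, flat fin signal with descending depth during glides, slow
# orientation drift, gravity in the accelerometer -- with ground-truth
# labels so every stage can be validated without deployed tag data.

#' Default gait simulation parameters
#'
#' Parameter set controlling the synthetic tag-signal generator. Defaults
#' reflect the study system: free-ranging squid fin at about 1.12 Hz
#' (between-animal s.d. 0.19 Hz), high-amplitude jets produce surge
#' acceleration pulses above the 0.10 g activity threshold at the end of the
#' fin downstroke, and glides are passive descents with a flat fin signal.
#'
#' @param fin_freq metachronal fin-beat frequency during finning (Hz).
#' @param fin_amplitude magnetometer modulation amplitude of one fin stroke
#'   (arbitrary field-strength units; fin--magnet coupling is uncalibrated,
#'   so only relative amplitudes are meaningful).
#' @param jet_cycle_freq fin cycle frequency during jetting (Hz); must be
#'   below `fin_freq` so that the two gaits are spectrally separable.
#' @param other_cycle_freq fin cycle frequency of low-frequency,
#'   low-acceleration ("other") movements (Hz); also below `fin_freq`.
#' @param lowfreq_amplitude magnetometer amplitude of the large, slow fin
#'   strokes used during jet and "other" cycles.
#' @param fin_mean_offset mean elevation of actively beating fins relative
#'   to the flat glide posture, as a fraction of the stroke amplitude; the
#'   magnet's mean position (and hence the mean field) shifts slightly
#'   upward whenever the fins are working.
#' @param jet_surge_peak peak dynamic surge acceleration of a jet pulse (g);
#'   must exceed 0.10 g, the activity/jet threshold.
#' @param jet_pulse_sd temporal width (Gaussian s.d., s) of a jet surge pulse.
#' @param glide_sink_rate passive sinking rate during glides (m s^-1,
#'   positive = descending).
#' @param climb_rate ascent rate during finning (m s^-1).
#' @param orientation_drift_scale scale of the smooth random-walk baseline in
#'   the magnetometer channels (units per sqrt(s)); small relative to
#'   `fin_amplitude` so slow body rotations never mimic fin strokes.
#' @param angle_drift_scale scale of the pitch/roll random walk rotating the
#'   1 g gravity vector in the accelerometer (rad per sqrt(s)).
#' @param noise_sd_mag per-channel Gaussian sensor noise s.d. in the
#'   magnetometer (default 5% of `fin_amplitude`).
#' @param noise_sd_accel per-channel Gaussian sensor noise s.d. in the
#'   accelerometer (g).
#' @return a named list of class `gait_params`.
#' @export
gait_params <- function(fin_freq = 1.12,
                        fin_amplitude = 1.0,
                        jet_cycle_freq = 0.40,
                        other_cycle_freq = 0.45,
                        lowfreq_amplitude = 2.0,
                        fin_mean_offset = 0.3,
                        jet_surge_peak = 0.20,
                        jet_pulse_sd = 0.08,
                        glide_sink_rate = 0.20,
                        climb_rate = 0.05,
                        orientation_drift_scale = 0.005,
                        angle_drift_scale = 0.02,
                        noise_sd_mag = 0.05,
                        noise_sd_accel = 0.01) {
  p <- list(
    fin_freq = fin_freq, fin_amplitude = fin_amplitude,
    jet_cycle_freq = jet_cycle_freq, other_cycle_freq = other_cycle_freq,
    lowfreq_amplitude = lowfreq_amplitude, fin_mean_offset = fin_mean_offset,
    jet_surge_peak = jet_surge_peak,
    jet_pulse_sd = jet_pulse_sd, glide_sink_rate = glide_sink_rate,
    climb_rate = climb_rate,
    orientation_drift_scale = orientation_drift_scale,
    angle_drift_scale = angle_drift_scale,
    noise_sd_mag = noise_sd_mag, noise_sd_accel = noise_sd_accel
  )
  bad <- !vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                 logical(1))
  if (any(bad)) {
    stop("non-finite gait parameters: ", paste(names(p)[bad], collapse = ", "))
  }
  if (p$jet_surge_peak <= 0.10) {
    stop("jet_surge_peak must exceed the 0.10 g surge threshold")
  }
  if (p$fin_freq <= p$jet_cycle_freq || p$fin_freq <= p$other_cycle_freq) {
    stop("fin_freq must exceed the jet and 'other' cycle frequencies")
  }
  structure(p, class = "gait_params")
}

.gait_states <- c("finning", "jet", "glide", "other")

#' Build a behaviour script
#'
#' A behaviour script is an ordered sequence of gait states with durations;
#' it is the ground-truth plan a synthetic deployment is generated from.
#'
#' @param states character vector of states, each one of `"finning"`,
#'   `"jet"`, `"glide"`, `"other"`.
#' @param durations segment durations in seconds (strictly positive), same
#'   length as `states`.
#' @param params a [gait_params()] set shared by all entries.
#' @param seed integer seed for all stochastic components of the simulation.
#' @param fin_freq optional per-entry fin-beat frequency overrides for
#'   finning entries (NA = use `params$fin_freq`).
#' @return object of class `behaviour_script`.
#' @export
behaviour_script <- function(states, durations, params = gait_params(),
                             seed = 1L, fin_freq = NULL) {
  states <- as.character(states)
  if (length(states) == 0L) stop("script must contain at least one entry")
  if (!all(states %in% .gait_states)) {
    stop("unknown state(s): ",
         paste(setdiff(states, .gait_states), collapse = ", "))
  }
  durations <- as.numeric(durations)
  if (length(durations) != length(states)) {
    stop("states and durations must have equal length")
  }
  if (!all(is.finite(durations)) || any(durations <= 0)) {
    stop("durations must be finite and strictly positive")
  }
  if (!inherits(params, "gait_params")) params <- do.call(gait_params, params)
  ff <- rep(NA_real_, length(states))
  if (!is.null(fin_freq)) ff[seq_along(fin_freq)] <- fin_freq
  ff[is.na(ff) & states == "finning"] <- params$fin_freq
  entries <- data.frame(
    state = states,
    start_s = cumsum(c(0, durations[-length(durations)])),
    duration_s = durations,
    fin_freq = ff
  )
  structure(list(entries = entries, params = params, seed = as.integer(seed)),
            class = "behaviour_script")
}

# Half-cosine on/off envelope confined to the first/last `ramp` seconds of a
# segment; keeps the fin modulation continuous across state boundaries.
segment_envelope <- function(tt, dur, ramp = 0.3) {
  env <- rep(1, length(tt))
  r <- min(ramp, dur / 2)
  if (r > 0) {
    a <- tt < r
    env[a] <- 0.5 * (1 - cos(pi * tt[a] / r))
    b <- tt > dur - r
    env[b] <- 0.5 * (1 - cos(pi * (dur - tt[b]) / r))
  }
  env
}

#' Simulate a tag recording from a behaviour script
#'
#' Generates synchronized fast (100 Hz accelerometer + magnetometer) and
#' slow (1 Hz depth + temperature) sensor streams. During finning the
#' magnetometer carries an additive sinusoid at the scripted fin-beat
#' frequency on top of a smooth orientation baseline; jet and "other"
#' segments carry large low-frequency fin cycles, with jets adding one
#' surge-acceleration pulse per cycle whose maximum falls at the end of the
#' fin downstroke; glides have a flat fin signal, sub-threshold dynamic
#' acceleration and monotonically increasing depth. The accelerometer
#' includes a 1 g gravity vector rotated by a slow orientation walk, so
#' dynamic-surge extraction is non-trivial.
#'
#' @param script a [behaviour_script()].
#' @param mass_kg animal wet mass (kg).
#' @param mantle_length_cm dorsal mantle length (cm), metadata only.
#' @param depth0 depth at the start of the recording (m).
#' @param temp_profile function mapping depth (m) to ambient temperature
#'   (degrees C); default is a constant 14.5 C, the mean ambient temperature
#'   at squid depth in the study region.
#' @param fs fast-stream sampling rate (Hz).
#' @return a list of class `tag_simulation` with elements `recording` (class
#'   `tag_recording`: `$fast`, `$slow` data frames plus animal metadata) and
#'   `truth` (class `ground_truth`: `$fin_events`, `$intervals`).
#' @export
simulate_recording <- function(script, mass_kg = 1.14, mantle_length_cm = 40,
                               depth0 = 100, temp_profile = NULL, fs = 100) {
  if (!inherits(script, "behaviour_script")) stop("script must be a behaviour_script")
  stopifnot_scalar(mass_kg, "mass_kg", positive = TRUE)
  p <- script$params
  ent <- script$entries
  total <- sum(ent$duration_s)
  n <- round(total * fs)
  if (n < 2L) stop("script too short to simulate")
  tt <- (seq_len(n) - 1L) / fs
  temp_profile <- temp_profile %||% function(d) rep(14.5, length(d))

  fmod <- numeric(n)       # fin-magnet modulation
  pulses <- numeric(n)     # jet surge pulses (g)
  vrate <- numeric(n)      # vertical rate (m/s, positive = down)
  fin_events <- numeric(0)

  for (i in seq_len(nrow(ent))) {
    st <- ent$state[i]
    t0 <- ent$start_s[i]
    dur <- ent$duration_s[i]
    idx <- which(tt >= t0 & tt < t0 + dur)
    tl <- tt[idx] - t0
    if (st == "glide") {
      vrate[idx] <- p$glide_sink_rate
      next
    }
    f <- switch(st,
      finning = ent$fin_freq[i],
      jet = p$jet_cycle_freq,
      other = p$other_cycle_freq
    )
    amp <- if (st == "finning") p$fin_amplitude else p$lowfreq_amplitude
    env <- segment_envelope(tl, dur)
    fmod[idx] <- fmod[idx] +
      amp * env * (p$fin_mean_offset + sin(2 * pi * f * tl))
    ncyc <- floor(dur * f)
    if (ncyc >= 1L) {
      crests <- t0 + (seq_len(ncyc) - 1 + 0.25) / f
      fin_events <- c(fin_events, crests)
    }
    if (st == "finning") vrate[idx] <- -p$climb_rate
    if (st == "jet" && ncyc >= 1L) {
      centers <- t0 + (seq_len(ncyc) - 1 + 0.75) / f
      for (cc in centers) {
        ridx <- which(abs(tt - cc) < 5 * p$jet_pulse_sd)
        pulses[ridx] <- pulses[ridx] +
          p$jet_surge_peak * exp(-(tt[ridx] - cc)^2 / (2 * p$jet_pulse_sd^2))
      }
    }
  }

  sim <- with_seed(script$seed, {
    drift <- function(scale) {
      moving_average(cumsum(stats::rnorm(n, 0, scale / sqrt(fs))), fs)
    }
    mnoise <- function() {
      if (p$noise_sd_mag > 0) stats::rnorm(n, 0, p$noise_sd_mag) else numeric(n)
    }
    anoise <- function() {
      if (p$noise_sd_accel > 0) stats::rnorm(n, 0, p$noise_sd_accel) else numeric(n)
    }
    mx <- 30 + drift(p$orientation_drift_scale) + fmod + mnoise()
    my <- 10 + drift(p$orientation_drift_scale) + mnoise()
    mz <- 20 + drift(p$orientation_drift_scale) + mnoise()
    theta <- drift(p$angle_drift_scale)
    phi <- drift(p$angle_drift_scale)
    ax <- sin(theta) + pulses + anoise()
    ay <- -cos(theta) * sin(phi) + anoise()
    az <- cos(theta) * cos(phi) + anoise()
    list(mx = mx, my = my, mz = mz, ax = ax, ay = ay, az = az)
  })

  depth <- pmax(0, depth0 + cumsum(vrate) / fs)
  slow_sec <- 0:(floor(total) - 1L)
  depth_slow <- depth[slow_sec * fs + 1L]
  fast <- data.frame(
    time_s = tt,
    ax_g = sim$ax, ay_g = sim$ay, az_g = sim$az,
    mx = sim$mx, my = sim$my, mz = sim$mz
  )
  slow <- data.frame(
    time_s = as.numeric(slow_sec),
    depth_m = depth_slow,
    temp_c = temp_profile(depth_slow)
  )
  recording <- structure(
    list(fast = fast, slow = slow, fs = fs,
         mass_kg = mass_kg, mantle_length_cm = mantle_length_cm),
    class = "tag_recording"
  )
  truth <- structure(
    list(fin_events = sort(fin_events),
         intervals = data.frame(start_s = ent$start_s,
                                end_s = ent$start_s + ent$duration_s,
                                state = ent$state)),
    class = "ground_truth"
  )
  structure(list(recording = recording, truth = truth, script = script),
            class = "tag_simulation")
}

#' @export
print.tag_recording <- function(x, ...) {
  cat(sprintf(
    "<tag_recording> %.1f s at %d Hz (fast), %d slow samples, mass %.2f kg\n",
    nrow(x$fast) / x$fs, x$fs, nrow(x$slow), x$mass_kg))
  invisible(x)
}

#' Inject orientation-change artefacts into glide intervals
#'
#' Adds slow, isolated baseline excursions to the magnetometer channels
#' during scripted glides. Such excursions mimic body-rotation artefacts:
#' they look like single fin-stroke peaks but have no neighbouring strokes,
#' which is exactly what the 4 s inter-fin-interval filter removes. Each
#' injected excursion is separated from every true fin event, and from every
#' other excursion, by more than 4 s on both sides; the ground truth is
#' unchanged and the excursion times are recorded in `$artefact_times`.
#'
#' @param sim a `tag_simulation` from [simulate_recording()].
#' @param n_events number of excursions to inject (>= 0).
#' @param seed integer seed for placement.
#' @param amplitude excursion height (same arbitrary units as the fin
#'   modulation).
#' @param width_s Gaussian s.d. of the excursion shape (s); the default
#'   gives a full width at half height near 0.7 s, slow relative to a fin
#'   stroke yet narrow enough for the peak detector to pick up.
#' @param clearance minimum separation (s) from true fin events, glide
#'   edges and other excursions.
#' @return the modified `tag_simulation`.
#' @export
simulate_orientation_artefacts <- function(sim, n_events, seed = 1L,
                                           amplitude = 2.5, width_s = 0.3,
                                           clearance = 4.5) {
  if (!inherits(sim, "tag_simulation")) stop("sim must be a tag_simulation")
  if (!is.numeric(n_events) || n_events < 0 || n_events != round(n_events)) {
    stop("n_events must be a non-negative integer")
  }
  if (n_events == 0) return(sim)
  iv <- sim$truth$intervals
  gl <- iv[iv$state == "glide", , drop = FALSE]
  cand <- numeric(0)
  for (i in seq_len(nrow(gl))) {
    lo <- gl$start_s[i] + clearance
    hi <- gl$end_s[i] - clearance
    if (hi > lo) cand <- c(cand, seq(lo, hi, by = 0.25))
  }
  if (length(cand) == 0L) {
    stop("no glide time available for ", n_events, " artefact(s)")
  }
  centers <- with_seed(seed, {
    pool <- sample(cand)
    acc <- numeric(0)
    for (c0 in pool) {
      if (length(acc) == n_events) break
      if (all(abs(acc - c0) >= clearance)) acc <- c(acc, c0)
    }
    acc
  })
  if (length(centers) < n_events) {
    stop("glide time available supports only ", length(centers),
         " artefact(s), not ", n_events)
  }
  tt <- sim$recording$fast$time_s
  for (cc in centers) {
    ridx <- which(abs(tt - cc) < 5 * width_s)
    bump <- amplitude * exp(-(tt[ridx] - cc)^2 / (2 * width_s^2))
    sim$recording$fast$mx[ridx] <- sim$recording$fast$mx[ridx] + bump
  }
  sim$artefact_times <- sort(centers)
  sim
}

#' Forward-simulate a swim-tunnel respirometry trial
#'
#' Generates a 1 Hz dissolved-oxygen trace declining linearly at the rate
#' implied by a known mass-specific metabolic rate plus a microbial
#' background slope, the generative model the respirometry stage inverts.
#'
#' @param rate_mg_kg_h mass-specific routine metabolic rate of the animal
#'   (mg O2 kg^-1 h^-1); 0 with `mass_kg = NA` gives a control trial.
#' @param mass_kg animal wet mass (kg), NA for controls.
#' @param volume_l respirometer system volume (l).
#' @param duration_s trial duration (s).
#' @param control_slope_mg_l_h microbial background DO slope (mg l^-1 h^-1,
#'   negative = declining).
#' @param do0 initial dissolved oxygen (mg l^-1).
#' @param temp_c water temperature (degrees C).
#' @param motor_level flume motor level (ordinal 1-5), metadata only.
#' @param noise_sd optical-sensor noise s.d. (mg l^-1).
#' @param seed integer seed for the sensor noise.
#' @return list of class `respirometry_trial` with `$data` (`time_s`,
#'   `do_mg_l`, `temp_c`) and trial metadata.
#' @export
simulate_respirometry_trial <- function(rate_mg_kg_h, mass_kg, volume_l = 1485,
                                        duration_s = 1800,
                                        control_slope_mg_l_h = -0.05,
                                        do0 = 8.0, temp_c = 18.8,
                                        motor_level = 1L, noise_sd = 0,
                                        seed = 1L) {
  stopifnot_scalar(volume_l, "volume_l", positive = TRUE)
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  animal_term <- if (is.na(mass_kg)) 0 else rate_mg_kg_h * mass_kg / volume_l
  slope_h <- control_slope_mg_l_h - animal_term   # mg/l per hour
  t <- 0:(floor(duration_s) - 1L)
  do <- do0 + slope_h * t / 3600
  if (noise_sd > 0) do <- do + with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  if (any(do <= 0)) stop("DO trace reaches zero; shorten the trial or raise do0")
  structure(
    list(data = data.frame(time_s = t, do_mg_l = do, temp_c = temp_c),
         mass_kg = mass_kg, volume_l = volume_l, temp_c = temp_c,
         motor_level = motor_level,
         true_slope_mg_l_h = slope_h,
         is_control = is.na(mass_kg)),
    class = "respirometry_trial"
  )
}
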
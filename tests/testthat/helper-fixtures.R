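# Shared synthetic fixtures and independent oracles used across the suite.

# 10-minute deployment mixing all four gait states, with long glides for
# artefact injection; fin_freq optionally overrides the finning frequency.
deployment_script <- function(seed, fin_freq = NA_real_) {
  behaviour_script(
    c("finning", "glide", "finning", "glide", "jet", "glide", "finning",
      "other", "glide"),
    c(150, 60, 150, 40, 30, 35, 85, 30, 20),
    seed = seed, fin_freq = rep(fin_freq, 9))
}

# 600 s script with scripted time budget 65.8% finning / 18.3% glide /
# 4.2% jet / 11.7% other; state durations are multiples of the 5 s
# classification window so the scripted fractions are recoverable.
budget_script <- function(seed) {
  behaviour_script(
    c("finning", "glide", "other", "glide", "finning", "glide", "jet",
      "glide", "finning", "glide", "other", "glide", "finning"),
    c(100, 20, 35, 15, 100, 20, 25, 15, 100, 20, 35, 20, 95),
    seed = seed)
}

scripted_fractions <- function(script) {
  d <- tapply(script$entries$duration_s, script$entries$state, sum)
  out <- as.numeric(d) / sum(script$entries$duration_s)
  names(out) <- names(d)
  out
}

detect_filtered <- function(sim, params = peak_params()) {
  filter_isolated_peaks(detect_peaks(condition_signal(sim$recording), params))
}

# Oracle: count of rising zero-crossings of the detrended signal equals the
# number of complete oscillation cycles.
rising_zero_crossings <- function(x) {
  xd <- x - mean(x)
  sum(xd[-length(xd)] <= 0 & xd[-1] > 0)
}

# Oracle: closed-form OLS slope as covariance/variance ratio.
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

make_events <- function(times) {
  out <- data.frame(time_s = times,
                    prominence = rep(1, length(times)),
                    width_s = rep(0.5, length(times)))
  class(out) <- c("fin_events", "data.frame")
  out
}
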
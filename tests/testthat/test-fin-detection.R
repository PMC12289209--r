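test_that("conditioning sums absolute axes and preserves constants", {
  n <- 200
  m <- cbind(rep(1, n), rep(-1, n), rep(1, n))
  sig <- condition_signal(m)
  expect_equal(sig$value, rep(3, n))
  expect_equal(nrow(sig), n)
})

test_that("a unit impulse spreads into a 1/30 plateau over 30 samples", {
  m <- matrix(0, nrow = 100, ncol = 3)
  m[50, 1] <- 1
  sig <- condition_signal(m, window = 30)
  expect_equal(sum(sig$value > 1e-12), 30)
  expect_equal(sig$value[sig$value > 1e-12], rep(1 / 30, 30))
})

test_that("conditioning preserves the fin-beat frequency", {
  sim <- simulate_recording(behaviour_script("finning", 120, seed = 4))
  sig <- condition_signal(sim$recording)
  sp <- stats::spec.pgram(stats::ts(sig$value - mean(sig$value),
                                    frequency = 100),
                          taper = 0, plot = FALSE)
  expect_equal(sp$freq[which.max(sp$spec)], 1.12, tolerance = 0.01 / 1.12)
})

test_that("detected count on clean sinusoids matches the zero-crossing oracle", {
  permissive <- peak_params(min_prominence = 0.2, min_width = 0.05,
                            max_width = 3)
  # small phase offset keeps samples off exact zeros of the sinusoid (crossing just after the record start)
  for (f in c(0.5, 0.8, 1.0, 1.3, 2.0)) {
    t <- seq(0, 60, by = 0.01)[-6001]
    x <- 2 + sin(2 * pi * f * t - 0.01)
    ev <- detect_peaks(x, permissive, fs = 100)
    expect_equal(nrow(ev), rising_zero_crossings(x))
  }
  # 1 Hz for 60 s: exactly 60 cycles
  t <- seq(0, 60, by = 0.01)[-6001]
  expect_equal(nrow(detect_peaks(2 + sin(2 * pi * t - 0.01), permissive,
                                 fs = 100)),
               60)
})

test_that("constant or sub-prominence signals yield no events", {
  expect_equal(nrow(detect_peaks(rep(5, 1000), fs = 100)), 0)
  t <- seq(0, 30, by = 0.01)
  weak <- 2 + 0.25 * sin(2 * pi * t)   # prominence 0.5
  expect_equal(
    nrow(detect_peaks(weak, peak_params(min_prominence = 0.6,
                                        min_width = 0.05, max_width = 2),
                      fs = 100)),
    0)
})

test_that("peak candidates carry topographic prominence and half-prominence width", {
  t <- seq(0, 20, by = 0.01)
  x <- 3 + sin(2 * pi * 1 * t)
  cand <- peak_candidates(x, fs = 100)
  interior <- cand[cand$time_s > 1 & cand$time_s < 19, ]
  # interior sinusoid peaks: prominence = 2 * amplitude, width = half period
  expect_equal(interior$prominence, rep(2, nrow(interior)), tolerance = 1e-6)
  expect_equal(interior$width_s, rep(0.5, nrow(interior)), tolerance = 0.01)
})

test_that("isolation filter removes only doubly-isolated events", {
  # single event in a long record: both gaps open -> removed
  expect_equal(nrow(filter_isolated_peaks(make_events(50))), 0)
  # gaps (2 s, 10 s): AND condition not met -> retained
  ev <- make_events(c(10, 12, 22))
  kept <- filter_isolated_peaks(ev)
  expect_equal(kept$time_s, c(10, 12))
  expect_equal(attr(kept, "removed_times"), 22)
  # dense train: nothing removed
  dense <- make_events(seq(0, 60, by = 0.9))
  expect_equal(nrow(filter_isolated_peaks(dense)), nrow(dense))
})

test_that("isolation filtering is idempotent", {
  for (seed in 1:5) {
    set.seed(seed)
    times <- sort(stats::runif(40, 0, 200))
    once <- filter_isolated_peaks(make_events(times))
    twice <- filter_isolated_peaks(once)
    expect_equal(twice$time_s, once$time_s)
  }
})

test_that("injected orientation artefacts are exactly the events the filter removes", {
  sim <- simulate_orientation_artefacts(
    simulate_recording(deployment_script(13)), 5, seed = 31)
  ev <- detect_peaks(condition_signal(sim$recording))
  filtered <- filter_isolated_peaks(ev)
  removed <- attr(filtered, "removed_times")
  # every artefact removed
  for (a in sim$artefact_times) {
    expect_true(any(abs(removed - a) < 0.5))
  }
  # nothing matched to a true fin event was removed
  for (r in removed) {
    expect_gt(min(abs(sim$truth$fin_events - r)), 0.25)
  }
  # all true events still recovered
  m <- match_events(filtered$time_s, sim$truth$fin_events)
  expect_equal(m$recall, 1)
})

test_that("event matching is one-to-one, nearest-first", {
  m <- match_events(c(1.0, 2.0, 3.0), c(1.1, 2.1), tol = 0.25)
  expect_equal(m$n_matched, 2L)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 2 / 3)
  # two references competing for one detection: only one match
  m2 <- match_events(1.0, c(0.9, 1.1), tol = 0.25)
  expect_equal(m2$n_matched, 1L)
  # nothing within tolerance
  expect_equal(match_events(1, 5, tol = 0.25)$n_matched, 0L)
})

test_that("grid training recovers a setting with perfect recall on clean segments", {
  sc <- behaviour_script(c("finning", "glide", "finning"), c(120, 10, 120),
                         seed = 17, fin_freq = c(0.9, NA, 1.25))
  sim <- simulate_recording(sc)
  sig <- condition_signal(sim$recording)
  tr <- sim$truth
  ann <- lapply(list(c(0, 120), c(130, 250)), function(b) {
    list(start = b[1], end = b[2],
         times = tr$fin_events[tr$fin_events >= b[1] & tr$fin_events < b[2]])
  })
  grid <- param_grid(min_prominence = c(0.2, 0.3, 0.5),
                     min_width = c(0.1, 0.2), max_width = c(1.0, 1.5))
  expect_equal(attr(grid, "n_combinations"), 12)
  opt <- optimize_peak_params(sig, ann, grid)
  expect_gt(nrow(opt$successes), 0)
  expect_true(all(opt$per_segment$recall == 1))
  # averaged setting lies within the grid's convex hull
  expect_gte(opt$params$min_prominence, 0.2)
  expect_lte(opt$params$max_width, 1.5)
  # deterministic
  opt2 <- optimize_peak_params(sig, ann, grid)
  expect_identical(opt$params, opt2$params)
})

test_that("training fails loudly when no combination can reach full recall", {
  sc <- behaviour_script("finning", 60, seed = 2)
  sim <- simulate_recording(sc)
  sig <- condition_signal(sim$recording)
  ann <- list(list(start = 0, end = 60,
                   times = sim$truth$fin_events))
  grid <- param_grid(min_prominence = c(50, 100), min_width = 0.1,
                     max_width = 1.5)
  expect_error(optimize_peak_params(sig, ann, grid),
               "no parameter combination.*recall")
})

test_that("training with require_no_extra rejects false-positive settings", {
  sc <- behaviour_script("finning", 90,
                         params = gait_params(noise_sd_mag = 0,
                                              noise_sd_accel = 0),
                         fin_freq = 1.0, seed = 23)
  sim <- simulate_recording(sc)
  sig <- condition_signal(sim$recording)
  ann <- list(list(start = 0, end = 90, times = sim$truth$fin_events))
  grid <- param_grid(min_prominence = c(0.001, 0.3), min_width = c(0.01, 0.1),
                     max_width = 1.5)
  strict <- optimize_peak_params(sig, ann, grid, require_no_extra = TRUE)
  lax <- optimize_peak_params(sig, ann, grid, require_no_extra = FALSE)
  expect_lte(nrow(strict$successes), nrow(lax$successes))
  expect_true(all(strict$per_segment$precision == 1))
})
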
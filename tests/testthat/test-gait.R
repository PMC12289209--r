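test_that("dynamic surge extraction removes the static gravity component", {
  expect_equal(extract_dynamic_surge(rep(1, 2000)), rep(0, 2000))
  # constant + 2 Hz sinusoid of 0.15 g: the 0.5 s separation window spans
  # exactly one period, so the sinusoid passes through unattenuated
  t <- seq(0, 30, by = 0.01)[-3001]
  x <- 1 + 0.15 * sin(2 * pi * 2 * t)
  dyn <- extract_dynamic_surge(x)
  interior <- dyn[101:2900]
  expect_equal(max(abs(interior)), 0.15, tolerance = 0.01)
  expect_lt(abs(mean(interior)), 0.01)
  expect_error(extract_dynamic_surge(numeric(0)), "empty")
})

test_that("1 s windows are labelled by the fin-event-or-surge rule", {
  surge <- rep(0.02, 300)           # 3 windows, quiet
  surge[150] <- 0.12                # window 2 exceeds threshold
  win <- label_windows(make_events(0.5), surge, fs = 100, threshold = 0.10)
  expect_equal(win$label, c("active", "active", "inactive"))
  expect_equal(win$has_fin_event, c(TRUE, FALSE, FALSE))
  expect_equal(win$max_surge[2], 0.12)
  # neither condition met
  win2 <- label_windows(numeric(0), rep(0.05, 100), fs = 100)
  expect_equal(win2$label, "inactive")
})

test_that("the surge threshold is applied to the absolute dynamic surge", {
  surge <- rep(0, 100); surge[50] <- -0.2
  win <- label_windows(numeric(0), surge, fs = 100)
  expect_equal(win$label, "active")
})

test_that("only inactive runs of at least 5 s become glides", {
  mkwin <- function(labels) {
    data.frame(start_s = seq_along(labels) - 1,
               has_fin_event = labels == "active",
               max_surge = 0, label = labels)
  }
  # 4 inactive windows alone: below the minimum, unclassified
  seg <- segment_states(mkwin(rep("inactive", 4)))
  expect_equal(seg$state, "unclassified")
  # 157 consecutive inactive seconds: one glide of 157 s
  seg2 <- segment_states(mkwin(c("active", rep("inactive", 157), "active")))
  gl <- seg2[seg2$state == "glide", ]
  expect_equal(gl$end_s - gl$start_s, 157)
  # alternating 1 s windows: no glides; lulls fold into one active run
  seg3 <- segment_states(mkwin(rep(c("active", "inactive"), 10)))
  expect_false(any(seg3$state == "glide"))
  expect_equal(sum(seg3$state == "active"), 1)
  # short inactive runs at the recording edge are not merged
  seg4 <- segment_states(mkwin(c(rep("inactive", 3), rep("active", 10))))
  expect_equal(seg4$state[1], "unclassified")
  # merging can be disabled
  seg5 <- segment_states(mkwin(c(rep("active", 3), rep("inactive", 2),
                                 rep("active", 3))),
                         merge_short_inactive = FALSE)
  expect_equal(seg5$state, c("active", "unclassified", "active"))
})

test_that("dominant frequency is exact to the padded resolution for supported frequencies", {
  cfg <- spectral_config()
  expect_equal(cfg$resolution_hz, 100 / 10500)
  t <- (0:499) / 100
  # >= 2 cycles per 5 s window: resolution-limited accuracy
  for (f in seq(0.4, 2.0, by = 0.2)) {
    for (ph in c(0, 1.1, 2.3)) {
      expect_lt(abs(dominant_frequency(sin(2 * pi * f * t + ph), cfg) - f),
                0.01)
    }
  }
  expect_lt(abs(dominant_frequency(sin(2 * pi * 1.12 * t), cfg) - 1.12),
            0.01)
  expect_lt(abs(dominant_frequency(sin(2 * pi * 0.40 * t), cfg) - 0.40),
            0.01)
  expect_error(dominant_frequency(rep(3, 500), cfg), "constant")
})

test_that("the bimodal split falls between the gait modes", {
  set.seed(42)
  freqs <- c(stats::rnorm(300, 1.1, 0.05), stats::rnorm(200, 0.4, 0.05))
  s <- find_split_frequency(freqs)
  expect_gt(s, 0.55)
  expect_lt(s, 0.95)
  # delta-like modes: split strictly between them
  freqs2 <- c(stats::rnorm(100, 0.4, 0.001), stats::rnorm(80, 1.2, 0.001))
  s2 <- find_split_frequency(freqs2)
  expect_gt(s2, 0.4)
  expect_lt(s2, 1.2)
})

test_that("unimodal distributions trigger the fallback with a warning", {
  set.seed(1)
  expect_warning(s <- find_split_frequency(stats::rnorm(100, 1.1, 0.05)),
                 "not bimodal")
  expect_equal(s, 0.75)
  expect_error(find_split_frequency(stats::rnorm(10, 1, 0.1)), "at least 50")
})

test_that("active 5 s windows follow the frequency/surge decision rule", {
  rule <- squidgait:::classify_window
  expect_equal(rule(1.1, 0.05, split = 0.7)$state, "finning")
  expect_false(rule(1.1, 0.05, split = 0.7)$jet_overlap)
  expect_equal(rule(0.45, 0.18, split = 0.7)$state, "jet")
  expect_equal(rule(0.45, 0.05, split = 0.7)$state, "other")
  fl <- rule(1.1, 0.15, split = 0.7)
  expect_equal(fl$state, "finning")
  expect_true(fl$jet_overlap)
})

test_that("classification recovers scripted states and flags fin-jet overlap", {
  sim <- simulate_recording(budget_script(3))
  ev <- detect_filtered(sim)
  cls <- classify_gaits(sim$recording, ev)
  expect_gt(cls$split_freq, 0.45)
  expect_lt(cls$split_freq, 1.12)
  seg <- cls$segments
  # per-state agreement with ground truth intervals
  iv <- sim$truth$intervals
  for (st in c("finning", "jet", "other")) {
    got <- sum(seg$end_s[seg$state == st] - seg$start_s[seg$state == st])
    want <- sum(iv$end_s[iv$state == st] - iv$start_s[iv$state == st])
    expect_lt(abs(got - want) / 600, 0.03)
  }
  # jet windows carry supra-threshold surge and low frequency
  jets <- seg[seg$state == "jet", ]
  expect_true(all(jets$max_surge > 0.10))
  expect_true(all(jets$dominant_freq < cls$split_freq))
})

test_that("segments partition the recording and fractions sum to one", {
  sim <- simulate_recording(budget_script(5))
  ev <- detect_filtered(sim)
  cls <- classify_gaits(sim$recording, ev)
  seg <- cls$segments
  expect_equal(seg$start_s[-1], seg$end_s[-nrow(seg)])
  expect_equal(min(seg$start_s), 0)
  expect_equal(max(seg$end_s), 600)
  tb <- compute_time_budget(seg, ev)
  expect_equal(sum(tb$fractions), 1, tolerance = 1e-9)
  expect_equal(tb$mean_fin_rate, 1.12, tolerance = 0.05)
})

test_that("raising thresholds never increases the corresponding fractions", {
  sim <- simulate_recording(budget_script(9))
  ev <- detect_filtered(sim)
  jet_frac <- vapply(c(0.10, 0.15, 0.30), function(thr) {
    cls <- classify_gaits(sim$recording, ev, surge_threshold = thr,
                          split = 0.78)
    compute_time_budget(cls$segments, ev)$fractions[["jet"]]
  }, numeric(1))
  expect_true(all(diff(jet_frac) <= 1e-9))
  glide_frac <- vapply(c(5, 10, 30), function(mg) {
    cls <- classify_gaits(sim$recording, ev, min_glide = mg, split = 0.78)
    compute_time_budget(cls$segments, ev)$fractions[["glide"]]
  }, numeric(1))
  expect_true(all(diff(glide_frac) <= 1e-9))
})

test_that("budget computation rejects non-partitioning segments", {
  bad <- data.frame(start_s = c(0, 50), end_s = c(60, 100),
                    state = c("finning", "glide"))
  expect_error(compute_time_budget(bad), "overlap")
  gap <- data.frame(start_s = c(0, 70), end_s = c(60, 100),
                    state = c("finning", "glide"))
  expect_error(compute_time_budget(gap), "gaps")
  solo <- data.frame(start_s = 0, end_s = 300, state = "glide")
  tb <- compute_time_budget(solo)
  expect_equal(tb$fractions[["glide"]], 1)
})
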
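test_that("DO slope regression is exact on linear traces", {
  t <- 0:1799
  d <- data.frame(time_s = t, do_mg_l = 8.0 - 1.0 * t / 3600)
  fit <- fit_do_slope(d)
  expect_equal(fit$slope_mg_l_h, -1.0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  flat <- data.frame(time_s = t, do_mg_l = rep(8, 1800))
  fit0 <- fit_do_slope(flat)
  expect_equal(fit0$slope_mg_l_h, 0)
  expect_equal(fit0$r_squared, 1)
  expect_error(fit_do_slope(data.frame(time_s = 0:60, do_mg_l = rep(8, 61))),
               "2 minutes")
  expect_error(fit_do_slope(data.frame(time_s = t,
                                       do_mg_l = c(NA, rep(8, 1799)))),
               "non-finite")
})

test_that("OLS slope equals the closed-form covariance/variance ratio", {
  for (seed in 1:10) {
    set.seed(seed)
    t <- 0:599
    y <- 8 - stats::runif(1, 0.1, 2) * t / 3600 + stats::rnorm(600, 0, 0.01)
    fit <- suppressWarnings(fit_do_slope(data.frame(time_s = t, do_mg_l = y)))
    expect_equal(fit$slope_mg_l_h, ols_slope(t, y) * 3600,
                 tolerance = 1e-12)
  }
})

test_that("the linearity QC warning fires below r-squared 0.98", {
  t <- 0:1799
  line <- 8.0 - 0.8 * t / 3600
  set.seed(5)
  z <- stats::rnorm(1800)
  # bisect the noise level to land r-squared near 0.95 (closed-form check)
  r2_at <- function(s) summary(stats::lm(line + s * z ~ t))$r.squared
  lo <- 0; hi <- 0.5
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (r2_at(mid) > 0.95) lo <- mid else hi <- mid
  }
  noisy <- data.frame(time_s = t, do_mg_l = line + hi * z)
  expect_warning(fit <- fit_do_slope(noisy), "below 0.98")
  expect_equal(fit$r_squared, 0.95, tolerance = 0.01)
  # clean traces pass silently
  expect_silent(fit_do_slope(data.frame(time_s = t, do_mg_l = line)))
})

test_that("metabolic rate arithmetic and fault detection follow the contract", {
  mr <- compute_metabolic_rate(-1.0, -0.1, volume_l = 1000, mass_kg = 3.0)
  expect_equal(mr$M_mg_h, 900)
  expect_equal(mr$mass_specific_mg_kg_h, 300)
  expect_equal(compute_metabolic_rate(-0.5, -0.5, 1000, 1)$M_mg_h, 0)
  expect_error(compute_metabolic_rate(-0.1, -0.5, 1000, 1), "steeper")
  # optional displacement correction shrinks the effective volume
  mr2 <- compute_metabolic_rate(-1.0, -0.1, 1000, 3.0,
                                subtract_animal_volume = TRUE)
  expect_equal(mr2$volume_used_l, 1000 - 3 / 1.06)
  expect_lt(mr2$M_mg_h, 900)
})

test_that("rates are linear in volume and slope difference, inverse in mass", {
  base <- compute_metabolic_rate(-1.2, -0.2, 500, 2)
  expect_equal(compute_metabolic_rate(-1.2, -0.2, 1000, 2)$M_mg_h,
               2 * base$M_mg_h)
  expect_equal(compute_metabolic_rate(-2.2, -0.2, 500, 2)$M_mg_h,
               2 * base$M_mg_h)
  expect_equal(compute_metabolic_rate(-1.2, -0.2, 500, 4)$mass_specific_mg_kg_h,
               base$mass_specific_mg_kg_h / 2)
})

test_that("a forward-simulated trial inverts to the generating rate", {
  # noise-free round trip: machine precision
  for (rate in c(204, 292, 391)) {
    tr <- simulate_respirometry_trial(rate, 1.5, volume_l = 1485,
                                      noise_sd = 0)
    ctrl <- simulate_respirometry_trial(0, NA_real_, noise_sd = 0)
    mr <- compute_metabolic_rate(fit_do_slope(tr)$slope_mg_l_h,
                                 fit_do_slope(ctrl)$slope_mg_l_h,
                                 1485, 1.5)
    expect_equal(mr$mass_specific_mg_kg_h, rate, tolerance = 1e-9)
  }
})

test_that("saturation screening flags sub-75% samples", {
  csat <- o2_saturation(18.8, 35)
  expect_gt(csat, 7); expect_lt(csat, 8.2)
  # colder water holds more oxygen
  expect_gt(o2_saturation(14.5), o2_saturation(18.8))
  # always above 80%: all valid
  expect_true(all(check_saturation(rep(0.8 * csat + 0.1, 100), 18.8)))
  # final third dips below 75%
  trace <- c(rep(0.9 * csat, 200), rep(0.7 * csat, 100))
  mask <- check_saturation(trace, 18.8)
  expect_equal(sum(!mask), 100)
  expect_true(all(!mask[201:300]))
  # degenerate threshold disables screening
  expect_true(all(check_saturation(trace, 18.8, min_frac = 0)))
})

test_that("the log-log scaling model passes through two exact points", {
  d <- data.frame(mass_kg = c(0.5, 2.525), rate_mg_kg_h = c(391, 204),
                  animal_id = c("a", "b"))
  m <- suppressWarnings(fit_allometric_model(d))
  expect_equal(predict(m, 0.5), 391, tolerance = 1e-9)
  expect_equal(predict(m, 2.525), 204, tolerance = 1e-9)
  expect_lt(m$slope, 0)
  expect_error(fit_allometric_model(
    data.frame(mass_kg = c(1, 1, 1), rate_mg_kg_h = c(300, 310, 290),
               animal_id = c("a", "b", "c"))),
    "unidentifiable")
})

test_that("predictions clamp to the fitted mass range with a warning", {
  d <- data.frame(mass_kg = rep(c(0.5, 1.0, 2.5), each = 2),
                  rate_mg_kg_h = c(390, 380, 300, 290, 210, 205),
                  animal_id = rep(c("a", "b", "c"), each = 2))
  m <- fit_allometric_model(d)
  expect_warning(p <- predict(m, 5), "outside")
  expect_equal(p, suppressWarnings(predict(m, 2.5)))
  expect_true(all(predict(m, c(0.6, 1.3, 2.2)) > 0))
})

test_that("a zero-slope generating process is covered by the interval", {
  hits <- 0
  for (s in 1:40) {
    set.seed(1000 + s)
    masses <- exp(stats::runif(7, log(0.5), log(2.5)))
    d <- do.call(rbind, lapply(1:7, function(i) {
      data.frame(mass_kg = masses[i],
                 rate_mg_kg_h = exp(log(290) + stats::rnorm(1, 0, 0.1) +
                                      stats::rnorm(2, 0, 0.08)),
                 animal_id = paste0("a", i))
    }))
    fit <- fit_allometric_model(d)
    if (fit$slope_ci95[1] <= 0 && 0 <= fit$slope_ci95[2]) hits <- hits + 1
  }
  expect_gte(hits, 33)   # ~95% nominal coverage over 40 draws
})

test_that("trial batches are background-corrected against the pooled controls", {
  trials <- list(
    simulate_respirometry_trial(300, 1.0, noise_sd = 0, seed = 1),
    simulate_respirometry_trial(250, 1.8, noise_sd = 0, seed = 2),
    simulate_respirometry_trial(0, NA_real_, noise_sd = 0, seed = 3)
  )
  res <- process_respirometry(trials)
  expect_equal(nrow(res), 2)
  expect_equal(res$rate_mg_kg_h, c(300, 250), tolerance = 1e-9)
  expect_equal(res$control_slope_mg_l_h, rep(-0.05, 2), tolerance = 1e-9)
  expect_error(process_respirometry(trials[1:2]), "control")
})
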
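# Swim-tunnel respirometry: DO-decline regression with QC, microbial
# background correction, air-saturation screening, and the log-log
# mass-scaling model used for field extrapolation.

#' Fit the dissolved-oxygen decline slope of a trial
#'
#' Ordinary least-squares regression of dissolved oxygen against time. A
#' sealed, well-mixed respirometer yields a linear decline; r-squared below
#' 0.98 triggers a quality-control warning (possible leakage, intrusion or
#' sensor fault).
#'
#' @param trial a `respirometry_trial` or data frame with `time_s` and
#'   `do_mg_l`.
#' @param r2_min r-squared QC threshold.
#' @return list with `slope_mg_l_h` (mg O2 l^-1 h^-1, negative when
#'   declining), `r_squared`, `n`.
#' @export
fit_do_slope <- function(trial, r2_min = 0.98) {
  d <- if (inherits(trial, "respirometry_trial")) trial$data else trial
  if (!all(is.finite(d$do_mg_l))) stop("non-finite DO values")
  if (diff(range(d$time_s)) < 120) stop("need at least 2 minutes of data")
  fit <- stats::lm(do_mg_l ~ time_s, data = d)
  slope <- unname(stats::coef(fit)[2L]) * 3600
  # suppressWarnings: summary.lm warns on numerically perfect fits, which
  # noise-free simulated traces legitimately produce
  r2 <- if (stats::var(d$do_mg_l) == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)
  if (r2 < r2_min) {
    warning(sprintf("DO trace r-squared %.3f below %.2f QC threshold",
                    r2, r2_min))
  }
  list(slope_mg_l_h = slope, r_squared = r2, n = nrow(d))
}

#' Metabolic rate from animal and control DO slopes
#'
#' The microbial background decline is subtracted from the animal trial
#' decline and the difference scaled by the system volume:
#' `M = (|animal slope| - |control slope|) * volume`. Optionally the animal
#' body volume (mass / tissue density) is deducted from the system volume;
#' for a ~1 kg squid in a 1485 l system this is a <0.1% effect and off by
#' default.
#'
#' @param animal_slope,control_slope DO slopes (mg O2 l^-1 h^-1); signs are
#'   ignored, magnitudes compared.
#' @param volume_l respirometer volume (l).
#' @param mass_kg animal wet mass (kg); NULL skips mass-specific output.
#' @param subtract_animal_volume deduct the animal's displacement volume.
#' @param tissue_density_kg_l squid tissue density for the displacement
#'   correction.
#' @return list of class `metabolic_rate`: `M_mg_h` (mg O2 h^-1),
#'   `mass_specific_mg_kg_h`, `control_slope_used`.
#' @export
compute_metabolic_rate <- function(animal_slope, control_slope = 0,
                                   volume_l, mass_kg = NULL,
                                   subtract_animal_volume = FALSE,
                                   tissue_density_kg_l = 1.06) {
  stopifnot_scalar(volume_l, "volume_l", positive = TRUE)
  a <- abs(animal_slope); c0 <- abs(control_slope)
  if (c0 > a + 1e-12) {
    stop("control decline steeper than animal decline: sensor or chamber fault")
  }
  vol <- volume_l
  if (subtract_animal_volume && !is.null(mass_kg)) {
    vol <- volume_l - mass_kg / tissue_density_kg_l
  }
  M <- (a - c0) * vol
  structure(list(
    M_mg_h = M,
    mass_specific_mg_kg_h = if (is.null(mass_kg)) NA_real_ else M / mass_kg,
    control_slope_used = control_slope,
    volume_used_l = vol
  ), class = "metabolic_rate")
}

#' Air-saturated oxygen concentration of seawater
#'
#' Benson--Krause equilibrium oxygen solubility (mg O2 l^-1) at 1 atm as a
#' function of temperature and salinity (the standard USGS/APHA
#' formulation).
#'
#' @param temp_c water temperature (degrees C).
#' @param salinity practical salinity (default 35, open-ocean seawater).
#' @return saturation concentration (mg O2 l^-1).
#' @export
o2_saturation <- function(temp_c, salinity = 35) {
  tk <- temp_c + 273.15
  lnC <- -139.34411 + 1.575701e5 / tk - 6.642308e7 / tk^2 +
    1.2438e10 / tk^3 - 8.621949e11 / tk^4 -
    salinity * (0.017674 - 10.754 / tk + 2140.7 / tk^2)
  exp(lnC)
}

#' Flag samples below an air-saturation floor
#'
#' Trials were managed to stay above 75% air saturation so that oxygen
#' limitation never depressed metabolic rate; samples below the floor
#' should be excluded or the trial truncated.
#'
#' @param do_mg_l dissolved-oxygen trace (mg l^-1).
#' @param temp_c trial temperature (scalar or per-sample).
#' @param salinity practical salinity.
#' @param min_frac saturation floor as a fraction of air saturation
#'   (0 disables screening).
#' @return logical vector, TRUE where the sample is valid.
#' @export
check_saturation <- function(do_mg_l, temp_c, salinity = 35, min_frac = 0.75) {
  csat <- o2_saturation(temp_c, salinity)
  do_mg_l >= min_frac * csat
}

#' Fit the log-log mass scaling model of metabolic rate
#'
#' Fits `log(rate) = a + b * log(mass)` with a per-animal random intercept
#' (animals contributed repeated swim trials). When every animal has a
#' single observation, or the mixed fit fails, an ordinary regression is
#' used with a warning. Natural logarithms are used throughout; predictions
#' are base-independent. The marginal r-squared is the fixed-effect variance
#' over the total (fixed + random + residual) variance.
#'
#' @param data data frame with columns `mass_kg`, `rate_mg_kg_h`
#'   (mass-specific routine metabolic rate) and `animal_id`.
#' @param reference_temp_c temperature the rates were measured at
#'   (degrees C); stored for downstream Q10 correction.
#' @return object of class `allometric_model` with elements `intercept`,
#'   `slope`, `slope_se`, `slope_df`, `slope_ci95`, `marginal_r2`,
#'   `mass_range_kg`, `reference_temp_c`, `fit`.
#' @export
fit_allometric_model <- function(data, reference_temp_c = 18.8) {
  need <- c("mass_kg", "rate_mg_kg_h", "animal_id")
  if (!all(need %in% names(data))) {
    stop("data must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(data) < 2L) stop("need at least 2 observations")
  if (length(unique(data$animal_id)) < 2L) stop("need at least 2 animals")
  if (stats::var(log(data$mass_kg)) == 0) {
    stop("all masses equal: slope unidentifiable")
  }
  if (any(data$rate_mg_kg_h <= 0) || any(data$mass_kg <= 0)) {
    stop("masses and rates must be positive")
  }
  if (nrow(data) < 3L) {
    warning("fewer than 3 observations; fit is exact-interpolation only")
  }
  d <- data.frame(ly = log(data$rate_mg_kg_h), lx = log(data$mass_kg),
                  id = factor(data$animal_id))
  repeated <- any(table(d$id) > 1L)
  fit <- NULL
  if (repeated) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(ly ~ lx + (1 | id), data = d,
                       control = lme4::lmerControl(calc.derivs = FALSE)))),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    if (repeated) {
      warning("mixed model could not be fitted; falling back to ordinary regression")
    } else {
      warning("all animals have single observations; using ordinary regression")
    }
    fit <- stats::lm(ly ~ lx, data = d)
    cf <- stats::coef(fit)
    se <- if (nrow(d) > 2L) summary(fit)$coefficients["lx", "Std. Error"]
          else NA_real_
    df <- stats::df.residual(fit)
    pred_fix <- stats::fitted(fit)
    var_ran <- 0
    sigma2 <- stats::sigma(fit)^2
  } else {
    cf <- lme4::fixef(fit)
    sm <- summary(fit)$coefficients
    se <- sm["lx", "Std. Error"]
    df <- sm["lx", "df"]
    pred_fix <- as.numeric(cbind(1, d$lx) %*% cf)
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_ran <- sum(vc$vcov[vc$grp != "Residual"])
    sigma2 <- stats::sigma(fit)^2
  }
  var_fix <- stats::var(pred_fix)
  marg_r2 <- var_fix / (var_fix + var_ran + sigma2)
  ci <- if (is.finite(se) && is.finite(df) && df > 0) {
    cf[["lx"]] + c(-1, 1) * stats::qt(0.975, df) * se
  } else c(NA_real_, NA_real_)
  structure(list(
    intercept = unname(cf[1L]),
    slope = unname(cf[2L]),
    slope_se = unname(se),
    slope_df = unname(df),
    slope_ci95 = ci,
    marginal_r2 = marg_r2,
    mass_range_kg = range(data$mass_kg),
    reference_temp_c = reference_temp_c,
    fit = fit
  ), class = "allometric_model")
}

#' Predict mass-specific metabolic rate from the scaling model
#'
#' Returns `exp(a + b * log(mass))` at the model's reference temperature.
#' Masses outside the fitted range are clamped to it with an extrapolation
#' warning (the scaling exponent is only supported inside the data).
#'
#' @param object an `allometric_model`.
#' @param mass_kg wet mass (kg), vectorized.
#' @param clamp clamp masses to the fitted range.
#' @param ... unused.
#' @return predicted mass-specific rate (mg O2 kg^-1 h^-1).
#' @export
predict.allometric_model <- function(object, mass_kg, clamp = TRUE, ...) {
  if (any(mass_kg <= 0)) stop("mass must be positive")
  rng <- object$mass_range_kg
  m <- mass_kg
  if (any(m < rng[1L] | m > rng[2L])) {
    warning(sprintf(
      "mass outside fitted range [%.3f, %.3f] kg; %s",
      rng[1L], rng[2L],
      if (clamp) "clamping to the range" else "extrapolating"))
    if (clamp) m <- pmin(pmax(m, rng[1L]), rng[2L])
  }
  exp(object$intercept + object$slope * log(m))
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf(
    "<allometric_model> log(rate) = %.3f %+.3f log(mass); marginal r2 = %.2f; mass %.3f-%.3f kg at %.1f C\n",
    x$intercept, x$slope, x$marginal_r2, x$mass_range_kg[1L],
    x$mass_range_kg[2L], x$reference_temp_c))
  invisible(x)
}

#' Process a set of respirometry trials into metabolic rates
#'
#' Fits DO slopes for every trial, averages the control (no-animal) slopes
#' into a microbial background, subtracts it from each animal trial and
#' normalizes by wet mass.
#'
#' @param trials list of `respirometry_trial` objects (or data frames with
#'   `time_s`, `do_mg_l`); controls identified by `is_control`/NA mass.
#' @param meta optional data frame overriding per-trial metadata
#'   (`mass_kg`, `volume_l`, `animal_id`, `is_control`), one row per trial.
#' @return data frame with one row per animal trial: `animal_id`,
#'   `mass_kg`, `slope_mg_l_h`, `r_squared`, `M_mg_h`, `rate_mg_kg_h`.
#' @export
process_respirometry <- function(trials, meta = NULL) {
  info <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    m <- list(
      mass_kg = if (!is.null(meta)) meta$mass_kg[i] else tr$mass_kg,
      volume_l = if (!is.null(meta)) meta$volume_l[i] else tr$volume_l,
      animal_id = if (!is.null(meta) && "animal_id" %in% names(meta))
        meta$animal_id[i] else (tr$animal_id %||% paste0("animal_", i))
    )
    m$is_control <- is.null(m$mass_kg) || is.na(m$mass_kg)
    m$slope <- fit_do_slope(tr)
    m
  })
  ctrl <- Filter(function(m) m$is_control, info)
  if (length(ctrl) == 0L) stop("no control (no-animal) trial present")
  control_slope <- mean(vapply(ctrl, function(m) m$slope$slope_mg_l_h,
                               numeric(1)))
  anim <- Filter(function(m) !m$is_control, info)
  do.call(rbind, lapply(anim, function(m) {
    mr <- compute_metabolic_rate(m$slope$slope_mg_l_h, control_slope,
                                 volume_l = m$volume_l, mass_kg = m$mass_kg)
    data.frame(animal_id = m$animal_id, mass_kg = m$mass_kg,
               slope_mg_l_h = m$slope$slope_mg_l_h,
               r_squared = m$slope$r_squared,
               control_slope_mg_l_h = control_slope,
               M_mg_h = mr$M_mg_h,
               rate_mg_kg_h = mr$mass_specific_mg_kg_h)
  }))
}
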
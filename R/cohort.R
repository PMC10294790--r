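# Synthetic virtual patients and the seeded cohort experiment.
#
# The virtual patient is a deliberately simple surrogate for a full
# physiological simulator: it reproduces only the externally relevant
# behaviours the dosing loop sees — hourly FT4 with a multiplicative
# circadian ripple, a TSH signal under negative (Hill-type) feedback fed
# back into the Michaelis-Menten production term with a one-hour lag,
# residual thyroid secretion at 17% of a normal gland, and an oral LT4
# bioavailability in [0.64, 0.83].

#' Generic patient interface used by the dosing loop
#'
#' `measure()` returns the visit FT4 sample (mean of the preceding 24 h of
#' hourly output); `advance()` simulates forward under a constant daily
#' dose and returns the updated patient plus the hourly log.
#'
#' @param patient a patient object
#' @param ... method arguments
#' @export
measure <- function(patient, ...) UseMethod("measure")

#' @rdname measure
#' @export
advance <- function(patient, ...) UseMethod("advance")

#' Gain calibration of the virtual-patient surrogate
#'
#' The surrogate's absolute scales are fixed once, in closed form, by two
#' anchors: (a) a full (100%) gland at a normal TSH of 5 mU/L sustains an
#' FT4 of 13 ng/L, which sets the endogenous-production scale; (b) the
#' nominal hypothyroid patient (17% residual gland, bioavailability 0.83)
#' on 100 ug/day settles at 13 ng/L, which sets the exogenous-gain scale.
#' The returned multiplicative factors are applied to the fitted `vmax` and
#' `kreac` of the plant parameter set.
#'
#' @param residual residual secretion fraction
#' @param tsh_max,tsh_half,hill TSH feedback parameters (see
#'   [virtual_patient()])
#' @param bioavailability nominal oral bioavailability
#' @param ft4_anchor anchor FT4 (ng/L)
#' @param tsh_normal normal-gland anchor TSH (mU/L)
#' @param dose_anchor anchor dose (ug/day)
#' @return named vector of factors `c(vmax = ..., kreac = ...)`
#' @export
patient_gain_calibration <- function(residual = 0.17, tsh_max = 10,
                                     tsh_half = 13, hill = 3,
                                     bioavailability = 0.83,
                                     ft4_anchor = 13, tsh_normal = 5,
                                     dose_anchor = 100) {
  nom <- thyroid_params()           # fitted nominal parameter set
  vmax_eff <- ft4_anchor * nom$ksec * (nom$km + tsh_normal) / tsh_normal
  tsh_at_anchor <- tsh_max * tsh_half^hill /
    (tsh_half^hill + ft4_anchor^hill)
  endo <- residual * vmax_eff * tsh_at_anchor /
    (nom$km + tsh_at_anchor) / nom$ksec
  exo_needed <- ft4_anchor - endo
  if (exo_needed <= 0) stop("anchors inconsistent: endogenous output alone exceeds the FT4 anchor")
  # mean exogenous T4 under daily impulses: bio * D / (24 kexc)
  x1_mean <- bioavailability * dose_anchor / LT4_MOLAR_MASS / (24 * nom$kexc)
  kreac_eff <- exo_needed * nom$ksec / x1_mean
  c(vmax = vmax_eff / nom$vmax, kreac = kreac_eff / nom$kreac)
}

#' Construct a virtual hypothyroid patient
#'
#' @param params a [thyroid_params()] object (the patient's plant constants;
#'   sampled around the fitted nominal set for cohort members)
#' @param bioavailability oral LT4 bioavailability, in [0.64, 0.83]
#' @param residual residual thyroid secretion as a fraction of a normal
#'   gland (0.17 for the modelled disease state)
#' @param circadian_amplitude fractional amplitude of the circadian FT4
#'   ripple (0 to 0.2)
#' @param circadian_phase acrophase offset in hours
#' @param tsh_max maximal pituitary TSH output (mU/L)
#' @param tsh_half FT4 at which TSH is half-maximal (ng/L)
#' @param hill Hill exponent of the TSH feedback
#' @param calibration gain factors from [patient_gain_calibration()]
#' @return object of class `virtual_patient`, initialised at its untreated
#'   steady state
#' @export
virtual_patient <- function(params = thyroid_params(),
                            bioavailability = 0.83,
                            residual = 0.17,
                            circadian_amplitude = 0.05,
                            circadian_phase = 8,
                            tsh_max = 10, tsh_half = 13, hill = 3,
                            calibration = patient_gain_calibration()) {
  stopifnot(inherits(params, "thyroid_params"))
  if (bioavailability < 0.64 || bioavailability > 0.83) {
    stop("bioavailability must lie in [0.64, 0.83]")
  }
  if (circadian_amplitude < 0 || circadian_amplitude > 0.2) {
    stop("circadian amplitude must lie in [0, 0.2]")
  }
  p <- structure(list(
    params = params,
    kreac_eff = unname(calibration["kreac"]) * params$kreac,
    vmax_eff = unname(calibration["vmax"]) * params$vmax,
    bioavailability = bioavailability,
    residual = residual,
    circadian_amplitude = circadian_amplitude,
    circadian_phase = circadian_phase,
    tsh_max = tsh_max, tsh_half = tsh_half, hill = hill,
    t = 0, x1 = 0, x2 = NA_real_, ft4_hist = NULL
  ), class = "virtual_patient")

  # untreated steady state: FT4 = residual production at the fed-back TSH
  f <- 5
  for (i in 1:200) {
    tsh <- patient_tsh(p, f)
    f <- p$residual * p$vmax_eff * tsh / (params$km + tsh) / params$ksec
  }
  p$x2 <- f
  hrs <- (-23):0
  p$ft4_hist <- f * (1 + circadian_amplitude *
                       sin(2 * pi * (hrs - circadian_phase) / 24))
  p
}

#' TSH response of the pituitary feedback model
#'
#' Monotone-decreasing Hill function of FT4:
#' `TSH = tsh_max * tsh_half^h / (tsh_half^h + FT4^h)`.
#'
#' @param patient a [virtual_patient()]
#' @param ft4 FT4 concentration(s), ng/L
#' @return TSH in mU/L
#' @export
tsh_response <- function(patient, ft4) {
  patient$tsh_max * patient$tsh_half^patient$hill /
    (patient$tsh_half^patient$hill + pmax(ft4, 0)^patient$hill)
}
patient_tsh <- tsh_response

#' @export
print.virtual_patient <- function(x, ...) {
  cat("virtual hypothyroid patient (synthetic surrogate)\n")
  cat(sprintf("  kexc = %.3g 1/h, T4 half-life %.2f d, bioavailability %.2f\n",
              x$params$kexc, log(2) / x$params$ksec / 24, x$bioavailability))
  cat(sprintf("  residual secretion %.0f%%, circadian amplitude %.0f%%\n",
              100 * x$residual, 100 * x$circadian_amplitude))
  cat(sprintf("  state: t = %g h, FT4 = %.2f ng/L, TSH = %.2f mU/L\n",
              x$t, x$x2, patient_tsh(x, x$x2)))
  invisible(x)
}

#' @rdname measure
#' @export
measure.virtual_patient <- function(patient, ...) {
  mean(utils::tail(patient$ft4_hist, 24))
}

#' @rdname measure
#' @param dose_ug constant daily dose over the advanced period (ug/day),
#'   taken as one impulse at the start of each day
#' @param hours number of hours to advance
#' @export
advance.virtual_patient <- function(patient, dose_ug = 0, hours = 672, ...) {
  pp <- patient$params
  E1 <- exp(-pp$kexc)
  E2 <- exp(-pp$ksec)
  cross <- patient$kreac_eff * (E1 - E2) / (pp$ksec - pp$kexc)
  D <- dose_ug / LT4_MOLAR_MASS * patient$bioavailability
  amp <- patient$circadian_amplitude
  phase <- patient$circadian_phase
  vres <- patient$residual * patient$vmax_eff

  x1 <- patient$x1
  x2 <- patient$x2
  ft4_prev <- patient$ft4_hist[length(patient$ft4_hist)]
  tvec <- patient$t + seq_len(hours)
  ft4 <- numeric(hours)
  ft4_smooth <- numeric(hours)
  tsh <- numeric(hours)
  for (i in seq_len(hours)) {
    if ((tvec[i] - 1) %% 24 == 0 && D > 0) x1 <- x1 + D
    tsh_i <- patient$tsh_max * patient$tsh_half^patient$hill /
      (patient$tsh_half^patient$hill + max(ft4_prev, 0)^patient$hill)
    u <- vres * tsh_i / (pp$km + tsh_i)
    x2 <- x2 * E2 + u / pp$ksec * (1 - E2) + cross * x1
    x1 <- x1 * E1
    ft4_i <- x2 * (1 + amp * sin(2 * pi * (tvec[i] - phase) / 24))
    ft4[i] <- ft4_i
    ft4_smooth[i] <- x2
    tsh[i] <- tsh_i
    ft4_prev <- ft4_i
  }
  patient$t <- patient$t + hours
  patient$x1 <- x1
  patient$x2 <- x2
  patient$ft4_hist <- utils::tail(c(patient$ft4_hist, ft4), 24)
  list(patient = patient,
       hourly = data.frame(time_h = tvec, ft4 = ft4,
                           ft4_smooth = ft4_smooth, tsh = tsh,
                           dose_ug = dose_ug))
}

#' Hourly FT4/TSH output of a patient under a daily dose series
#'
#' Convenience wrapper: advances a freshly initialised copy of the patient
#' through the given per-day dose series and returns the hourly log.
#'
#' @param patient a [virtual_patient()]
#' @param daily_ug per-day dose series (ug/day)
#' @return data.frame with `time_h`, `ft4`, `tsh`, `dose_ug`
#' @export
patient_output <- function(patient, daily_ug) {
  chunks <- vector("list", length(daily_ug))
  for (d in seq_along(daily_ug)) {
    adv <- advance(patient, dose_ug = daily_ug[d], hours = 24)
    patient <- adv$patient
    chunks[[d]] <- adv$hourly
  }
  do.call(rbind, chunks)
}

#' Bring a patient to the steady state matched to a constant dose
#'
#' @param patient a [virtual_patient()]
#' @param dose_ug constant daily dose (ug/day)
#' @param burn_in_h burn-in length in hours
#' @export
patient_at_steady_state <- function(patient, dose_ug, burn_in_h = 24 * 240) {
  adv <- advance(patient, dose_ug = dose_ug, hours = burn_in_h)
  p <- adv$patient
  p$t <- 0
  p
}

#' Cohort configuration
#'
#' Sampling distributions of the virtual-patient generator: the oral
#' elimination rate is uniform over its uncertainty interval, the T4
#' half-life uniform over 9-10 days, the three fitted constants log-normal
#' around the nominal set with a 30% coefficient of variation, and the
#' bioavailability uniform over [0.64, 0.83].
#'
#' @param n number of patients
#' @param seed master seed (patient `i` is deterministic under
#'   `(seed, i)` regardless of `n`)
#' @param n_visits monthly visits per patient
#' @param reference constant reference FT4 (ng/L)
#' @param kexc_range uniform range of the oral elimination rate (1/h)
#' @param half_life_days uniform range of the T4 half-life (days)
#' @param cv log-normal coefficient of variation of `kreac`, `km`, `vmax`
#' @param bioavailability_range uniform range of oral bioavailability
#' @param circadian_amplitude fixed fractional ripple amplitude
#' @export
cohort_config <- function(n = 50, seed = 42, n_visits = 12, reference = 13,
                          kexc_range = c(0.16, 0.36),
                          half_life_days = c(9, 10), cv = 0.3,
                          bioavailability_range = c(0.64, 0.83),
                          circadian_amplitude = 0.05) {
  if (n < 1) stop("the cohort needs at least one patient")
  structure(list(n = n, seed = seed, n_visits = n_visits,
                 reference = reference, kexc_range = kexc_range,
                 half_life_days = half_life_days, cv = cv,
                 bioavailability_range = bioavailability_range,
                 circadian_amplitude = circadian_amplitude),
            class = "cohort_config")
}

#' Generate one seeded virtual patient
#'
#' @param config a [cohort_config()]
#' @param index patient index (1-based)
#' @return a [virtual_patient()]
#' @export
generate_patient <- function(config, index) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed((config$seed + 7919L * as.integer(index)) %% .Machine$integer.max)
  nom <- thyroid_params()
  sdlog <- sqrt(log(1 + config$cv^2))
  draw_ln <- function(m) m * stats::rlnorm(1, meanlog = -sdlog^2 / 2,
                                           sdlog = sdlog)
  kexc <- stats::runif(1, config$kexc_range[1], config$kexc_range[2])
  half_life <- stats::runif(1, config$half_life_days[1],
                            config$half_life_days[2]) * 24
  params <- thyroid_params(kreac = draw_ln(nom$kreac),
                           km = draw_ln(nom$km),
                           vmax = draw_ln(nom$vmax),
                           kexc = kexc, ksec = log(2) / half_life)
  virtual_patient(params,
                  bioavailability = stats::runif(
                    1, config$bioavailability_range[1],
                    config$bioavailability_range[2]),
                  circadian_amplitude = config$circadian_amplitude,
                  circadian_phase = stats::runif(1, 0, 24))
}

#' Run the closed-loop cohort experiment
#'
#' Treats every generated patient with the shared controller and therapy
#' limits and aggregates the monthly mean and standard deviation of the
#' measured FT4 (at the end of each month) and of the prescribed dose
#' across patients.
#'
#' @param config a [cohort_config()]
#' @param ctrl controller shared across patients; default: designed at the
#'   nominal parameter set
#' @param limits a [therapy_limits()]
#' @return object of class `cohort_summary` with `monthly`
#'   (month, ft4_mean, ft4_std, dose_mean, dose_std), `patients`
#'   (per-patient final FT4/dose and sampled parameters), and `failures`
#' @export
run_cohort <- function(config = cohort_config(),
                       ctrl = design_controller(
                         discretize_impulse_invariant(thyroid_params())),
                       limits = therapy_limits()) {
  stopifnot(inherits(config, "cohort_config"))
  refs <- reference_schedule(0, config$reference)
  ft4 <- matrix(NA_real_, config$n, config$n_visits)
  dose <- matrix(NA_real_, config$n, config$n_visits)
  patients <- vector("list", config$n)
  failures <- integer(0)
  for (i in seq_len(config$n)) {
    pat <- generate_patient(config, i)
    res <- tryCatch(
      run_closed_loop(pat, ctrl, refs, limits, n_visits = config$n_visits),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, i)
      patients[[i]] <- data.frame(patient = i, kexc = pat$params$kexc,
                                  ksec = pat$params$ksec,
                                  kreac = pat$params$kreac,
                                  km = pat$params$km, vmax = pat$params$vmax,
                                  bioavailability = pat$bioavailability,
                                  final_ft4 = NA_real_, final_dose = NA_real_)
      next
    }
    # month-k FT4 = measurement at the END of month k (visit k+1 / final)
    ft4[i, ] <- c(res$visits$ft4[-1], res$final_ft4)
    dose[i, ] <- res$visits$dose
    patients[[i]] <- data.frame(patient = i, kexc = pat$params$kexc,
                                ksec = pat$params$ksec,
                                kreac = pat$params$kreac,
                                km = pat$params$km, vmax = pat$params$vmax,
                                bioavailability = pat$bioavailability,
                                final_ft4 = res$final_ft4,
                                final_dose = res$visits$dose[config$n_visits])
  }
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  monthly <- data.frame(
    month = seq_len(config$n_visits),
    ft4_mean = colMeans(ft4, na.rm = TRUE),
    ft4_std = apply(ft4, 2, function(x) sd0(x[!is.na(x)])),
    dose_mean = colMeans(dose, na.rm = TRUE),
    dose_std = apply(dose, 2, function(x) sd0(x[!is.na(x)]))
  )
  structure(list(monthly = monthly,
                 patients = do.call(rbind, patients),
                 failures = failures,
                 config = config),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  m <- x$monthly
  n_ok <- sum(!is.na(x$patients$final_ft4))
  cat(sprintf("cohort of %d virtual patients (%d completed, seed %d)\n",
              x$config$n, n_ok, x$config$seed))
  cat(sprintf("  month 1:  FT4 %5.2f +/- %.2f ng/L, dose %6.1f +/- %.1f ug\n",
              m$ft4_mean[1], m$ft4_std[1], m$dose_mean[1], m$dose_std[1]))
  nm <- nrow(m)
  cat(sprintf("  month %d: FT4 %5.2f +/- %.2f ng/L, dose %6.1f +/- %.1f ug\n",
              nm, m$ft4_mean[nm], m$ft4_std[nm], m$dose_mean[nm],
              m$dose_std[nm]))
  lo <- 9.2; hi <- 16
  cat(sprintf("  final FT4 within [%.1f, %.1f]: %d/%d patients\n", lo, hi,
              sum(x$patients$final_ft4 >= lo & x$patients$final_ft4 <= hi,
                  na.rm = TRUE), x$config$n))
  invisible(x)
}

#' Write cohort outputs (summary CSV and per-patient JSON)
#' @param summary a [run_cohort()] result
#' @param summary_csv path for `month, ft4_mean, ft4_std, dose_mean, dose_std`
#' @param patients_json optional path for the sampled per-patient parameters
#' @export
write_cohort_summary <- function(summary, summary_csv,
                                 patients_json = NULL) {
  utils::write.csv(summary$monthly, summary_csv, row.names = FALSE)
  if (!is.null(patients_json)) {
    jsonlite::write_json(summary$patients, patients_json, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(summary)
}
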
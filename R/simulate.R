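# Exact simulation of the two-state plant under impulsive daily dosing.
#
# Between events the system is linear with piecewise-constant TSH, so each
# hourly step has a closed-form solution: x1 decays as exp(-kexc*t), x2
# combines its own decay, the constant-TSH forcing
# vmax*TSH/(km+TSH)/ksec * (1 - exp(-ksec*t)), and the two-exponential
# cross term driven by x1.  The recursions are vectorised with
# stats::filter, so the propagation is exact to round-off (no ODE solver).

#' Impulsive oral dose schedule
#'
#' @param time_h dose times in hours from therapy start (strictly increasing)
#' @param dose_ug dose sizes in micrograms (nonnegative)
#' @return object of class `dose_schedule`
#' @export
dose_schedule <- function(time_h = numeric(), dose_ug = numeric()) {
  if (length(time_h) != length(dose_ug)) stop("time_h and dose_ug lengths differ")
  if (length(time_h) > 1 && any(diff(time_h) <= 0)) {
    stop("dose times must be strictly increasing")
  }
  if (any(dose_ug < 0)) stop("doses must be nonnegative")
  structure(data.frame(time_h = as.numeric(time_h), dose_ug = as.numeric(dose_ug)),
            class = c("dose_schedule", "data.frame"))
}

#' Daily dosing schedule from per-day dose levels
#'
#' One impulse per day at hour 0, 24, 48, ... with the given daily amounts.
#'
#' @param daily_ug vector of daily doses; recycled amounts are not allowed,
#'   supply one value per day
#' @export
daily_schedule <- function(daily_ug) {
  n <- length(daily_ug)
  dose_schedule(time_h = 24 * (seq_len(n) - 1), dose_ug = daily_ug)
}

#' Staircase dosing used for model identification
#'
#' Monthly dose steps (default 50/80/110 ug/day over three 30-day months),
#' the standard record on which the patient-specific parameters are fitted.
#'
#' @param levels_ug per-month daily dose (ug/day)
#' @param days_per_level days each level is held
#' @export
staircase_schedule <- function(levels_ug = c(50, 80, 110), days_per_level = 30) {
  daily_schedule(rep(levels_ug, each = days_per_level))
}

#' Simulate the two-state plant
#'
#' Propagates `x1` (exogenous T4, umol) and `x2` (FT4, ng/L) on an hourly
#' grid `0..t_end` under impulsive oral doses and a piecewise-constant
#' (zero-order-hold, hourly) TSH signal.  Doses are converted
#' ug -> umol via the LT4 molar mass and multiplied by `bioavailability`
#' before entering `x1`.  Grid values at dose times are post-dose.
#'
#' @param params a [thyroid_params()] object
#' @param doses a [dose_schedule()]; dose times must lie on the hourly grid
#' @param tsh TSH values in mU/L: a single number, a vector of length
#'   `t_end + 1` (value held on each hour interval; the final entry is
#'   only used for reporting), or a function of time in hours
#' @param t_end final time in hours (integer)
#' @param x0 initial state `c(x1, x2)`, nonnegative
#' @param bioavailability fraction of the oral dose absorbed
#' @return a `data.frame` of class `plant_trajectory` with columns
#'   `time_h`, `x1_umol`, `ft4`, `tsh`
#' @export
simulate_plant <- function(params, doses, tsh, t_end,
                           x0 = c(0, 0), bioavailability = 1) {
  stopifnot(inherits(params, "thyroid_params"))
  t_end <- as.integer(t_end)
  if (t_end < 1) stop("t_end must be at least 1 hour")
  tgrid <- 0:t_end
  n <- length(tgrid)

  if (is.function(tsh)) tsh <- tsh(tgrid)
  if (length(tsh) == 1L) tsh <- rep(tsh, n)
  if (length(tsh) != n) stop("tsh must have one value per grid hour (t_end + 1)")
  if (any(!is.finite(tsh)) || any(tsh < 0)) stop("TSH must be finite and nonnegative")
  if (any(x0 < 0)) stop("initial state must be nonnegative")
  if (bioavailability <= 0 || bioavailability > 1) {
    stop("bioavailability must lie in (0, 1]")
  }

  imp <- numeric(n)
  if (nrow(doses) > 0) {
    idx <- match(doses$time_h, tgrid)
    if (anyNA(idx)) stop("dose times must lie on the hourly grid within [0, t_end]")
    imp[idx] <- imp[idx] + doses$dose_ug / LT4_MOLAR_MASS * bioavailability
  }

  E1 <- exp(-params$kexc)
  E2 <- exp(-params$ksec)

  # x1[k] = sum_{j<=k} imp[j] E1^(k-j), seeded with x0[1] at t = 0
  z <- imp; z[1] <- z[1] + x0[1]
  x1 <- as.numeric(stats::filter(z, E1, method = "recursive"))

  # forcing on each interval [k, k+1): endogenous production at the held TSH
  # plus the cross term from the interval-start value of x1
  u <- params$vmax * tsh / (params$km + tsh)
  force <- u[-n] / params$ksec * (1 - E2) +
    params$kreac * x1[-n] * (E1 - E2) / (params$ksec - params$kexc)
  x2 <- c(x0[2],
          as.numeric(stats::filter(force, E2, method = "recursive",
                                   init = x0[2])))

  structure(
    data.frame(time_h = tgrid, x1_umol = x1, ft4 = x2, tsh = tsh),
    class = c("plant_trajectory", "data.frame")
  )
}

#' Equilibrium of the plant under a constant infusion rate
#'
#' For a constant dose rate `d` (umol/h) and constant TSH the fixed point of
#' the dynamics is `x1* = d/kexc` and
#' `x2* = (vmax*TSH/(km+TSH) + kreac*x1*)/ksec`.
#'
#' @param params a [thyroid_params()] object
#' @param d_umol_h constant infusion rate (umol/h)
#' @param tsh constant TSH (mU/L)
#' @export
plant_equilibrium <- function(params, d_umol_h, tsh) {
  x1 <- d_umol_h / params$kexc
  x2 <- (params$vmax * tsh / (params$km + tsh) + params$kreac * x1) / params$ksec
  c(x1 = x1, x2 = x2)
}

#' Write / read a trajectory as CSV
#'
#' Columns `time_h`, `x1_umol`, `ft4`, `tsh`; comma separated, '.' decimal.
#' @param traj a trajectory from [simulate_plant()]
#' @param path file path
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("time_h", "x1_umol", "ft4", "tsh")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_h", "x1_umol", "ft4", "tsh")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns time_h, x1_umol, ft4, tsh")
  }
  structure(df[, need], class = c("plant_trajectory", "data.frame"))
}

#' Write / read a dose schedule as CSV (columns time_h, dose_ug)
#' @param doses a [dose_schedule()]
#' @param path file path
#' @export
write_schedule <- function(doses, path) {
  utils::write.csv(as.data.frame(doses), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_h", "dose_ug") %in% names(df))) {
    stop("schedule CSV must have columns time_h, dose_ug")
  }
  dose_schedule(df$time_h, df$dose_ug)
}
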
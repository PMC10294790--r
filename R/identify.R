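# Least-squares identification of the patient-specific parameters
# (kreac, km, vmax) from dosing / TSH / FT4 records, with kexc and ksec
# fixed from literature half-life values.
#
# The search is a bounded log-parameterised Nelder-Mead multistart.  Because
# the model output is linear in kreac and vmax once km is fixed, the best
# simplex solution is refined by a variable-projection polish: a 1-D profiled
# search over km with an inner linear least-squares solve for (kreac, vmax).

#' Hourly identification record
#'
#' @param time_h hourly time grid 0..N
#' @param dose_ug impulsive dose administered at each grid hour (0 when none)
#' @param tsh measured/recorded TSH (mU/L), held per hour
#' @param ft4 observed FT4 output (ng/L)
#' @return object of class `ident_data`
#' @export
ident_data <- function(time_h, dose_ug, tsh, ft4) {
  n <- length(time_h)
  if (n < 2) stop("an identification record needs at least two samples")
  if (length(dose_ug) != n || length(tsh) != n || length(ft4) != n) {
    stop("time_h, dose_ug, tsh and ft4 must have equal lengths")
  }
  if (any(diff(time_h) != 1)) stop("the record must be hourly (unit time steps)")
  if (any(tsh < 0)) stop("TSH must be nonnegative")
  structure(data.frame(time_h = time_h, dose_ug = dose_ug,
                       tsh = tsh, ft4 = ft4),
            class = c("ident_data", "data.frame"))
}

ident_schedule <- function(data) {
  on <- data$dose_ug > 0
  dose_schedule(data$time_h[on], data$dose_ug[on])
}

ident_simulate <- function(p, data, kexc, ksec, x0) {
  params <- thyroid_params(kreac = p[["kreac"]], km = p[["km"]],
                           vmax = p[["vmax"]], kexc = kexc, ksec = ksec)
  simulate_plant(params, ident_schedule(data), data$tsh,
                 t_end = max(data$time_h), x0 = x0)$ft4
}

#' Sum-of-squares identification cost
#'
#' `J(p) = sum_i (y(i) - ym(i))^2` where `ym` is the model FT4 output under
#' the candidate parameters `p = (kreac, km, vmax)`, the recorded doses and
#' the recorded TSH.  The initial model state is `(0, ft4[1])`: a
#' therapy-naive exogenous compartment with the first observed FT4 sample.
#'
#' @param p named vector or list with `kreac`, `km`, `vmax`
#' @param data an [ident_data()] record
#' @param kexc,ksec fixed elimination rates (not identified)
#' @return scalar cost
#' @export
ident_cost <- function(p, data, kexc = KEXC_NOMINAL, ksec = KSEC_NOMINAL) {
  p <- unlist(p)[c("kreac", "km", "vmax")]
  if (any(!is.finite(p)) || any(p <= 0)) stop("parameters must be positive")
  ym <- ident_simulate(p, data, kexc, ksec, x0 = c(0, data$ft4[1]))
  sum((data$ft4 - ym)^2)
}

# Linear least-squares for (kreac, vmax) at fixed km; the model output
# decomposes as decay + kreac * S1 + vmax * S2(km).
ident_linear_fit <- function(km, data, kexc, ksec) {
  t_end <- max(data$time_h)
  eps <- .Machine$double.xmin   # effectively-zero stand-in for the off component
  E2 <- exp(-ksec * (data$time_h - data$time_h[1]))
  decay <- data$ft4[1] * E2
  p1 <- thyroid_params(kreac = 1, km = km, vmax = eps, kexc = kexc, ksec = ksec)
  s1 <- simulate_plant(p1, ident_schedule(data), data$tsh, t_end)$ft4
  p2 <- thyroid_params(kreac = eps, km = km, vmax = 1, kexc = kexc, ksec = ksec)
  s2 <- simulate_plant(p2, dose_schedule(), data$tsh, t_end)$ft4
  rhs <- data$ft4 - decay
  fit <- stats::lm.fit(cbind(s1, s2), rhs)
  cf <- fit$coefficients
  list(kreac = unname(cf[1]), vmax = unname(cf[2]),
       J = sum(fit$residuals^2))
}

#' Identify patient-specific plant parameters
#'
#' Minimises [ident_cost()] over `0 < p <= bounds` with a derivative-free
#' simplex search in log-parameter space (positivity by construction) plus a
#' quadratic penalty above the upper bounds, restarted from jittered initial
#' guesses, followed by a variable-projection polish over `km`.
#'
#' @param data an [ident_data()] record; the TSH record must vary over time,
#'   otherwise `km` and `vmax` are not separately identifiable (only the
#'   lumped production `vmax*TSH/(km+TSH)` is determined) and a warning is
#'   issued
#' @param init named vector of starting values (`kreac`, `km`, `vmax`)
#' @param bounds named vector of upper bounds; defaults to 10x the nominal
#'   (fitted) parameter set
#' @param kexc,ksec fixed elimination rates
#' @param restarts number of jittered restarts after the initial run
#' @param seed optional seed for the restart jitter
#' @return list with `p` (named estimate), `J`, `converged`, `evaluations`
#' @export
identify_params <- function(data, init, bounds = NULL,
                            kexc = KEXC_NOMINAL, ksec = KSEC_NOMINAL,
                            restarts = 3, seed = NULL) {
  nominal <- c(kreac = 7.25, km = 9.504e3, vmax = 2.19e-4)
  if (is.null(bounds)) bounds <- 10 * nominal
  init <- unlist(init)[names(nominal)]
  bounds <- unlist(bounds)[names(nominal)]
  if (any(!is.finite(init)) || any(init <= 0) || any(init > bounds)) {
    stop("init must be strictly positive and within the upper bounds")
  }
  tsh_range <- diff(range(data$tsh))
  if (tsh_range <= 1e-10 * (1 + max(abs(data$tsh)))) {
    warning("TSH is constant over the record: km and vmax are not separately ",
            "identifiable (only the lumped term vmax*TSH/(km+TSH) is determined)")
  }
  if (!is.null(seed)) set.seed(seed)

  evals <- 0L
  objective <- function(lp) {
    p <- exp(lp); names(p) <- names(nominal)
    evals <<- evals + 1L
    pen <- sum(pmax(0, (p - bounds) / bounds)^2)
    ident_cost(pmin(p, bounds), data, kexc, ksec) * (1 + pen) + 1e8 * pen
  }

  starts <- list(log(init))
  for (r in seq_len(restarts)) {
    starts[[r + 1L]] <- log(init) + stats::rnorm(3, sd = 0.1)
  }
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    fit <- stats::optim(s, objective, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      converged <- fit$convergence == 0
    }
  }
  p_hat <- pmin(exp(best$par), bounds)
  names(p_hat) <- names(nominal)
  J_hat <- ident_cost(p_hat, data, kexc, ksec)

  # variable-projection polish: profile J over km, inner linear LS
  if (tsh_range > 1e-10 * (1 + max(abs(data$tsh)))) {
    prof <- function(lkm) {
      evals <<- evals + 1L
      ident_linear_fit(exp(lkm), data, kexc, ksec)$J
    }
    lo <- log(max(p_hat[["km"]] / 50, 1e-12))
    hi <- log(min(p_hat[["km"]] * 50, bounds[["km"]]))
    opt <- stats::optimize(prof, c(lo, hi), tol = 1e-12)
    lin <- ident_linear_fit(exp(opt$minimum), data, kexc, ksec)
    p_pol <- c(kreac = lin$kreac, km = exp(opt$minimum), vmax = lin$vmax)
    if (all(is.finite(p_pol)) && all(p_pol > 0) && all(p_pol <= bounds)) {
      J_pol <- ident_cost(p_pol, data, kexc, ksec)
      if (J_pol < J_hat) {
        p_hat <- p_pol
        J_hat <- J_pol
        converged <- TRUE
      }
    }
  }

  J_init <- ident_cost(init, data, kexc, ksec)
  if (J_hat > J_init) {   # never worse than the starting point
    p_hat <- init
    J_hat <- J_init
  }
  list(p = p_hat, J = J_hat, converged = converged, evaluations = evals)
}

#' Synthetic TSH record for identification experiments
#'
#' A smooth, time-varying TSH trace emulating an undertreated hypothyroid
#' patient entering therapy: an elevated baseline decaying towards a treated
#' level plus a slow weekly modulation.  Values stay within 15-90 mU/L over
#' a 90-day record.
#'
#' @param t time in hours
#' @export
synthetic_tsh <- function(t) {
  20 + 70 * exp(-t / 720) + 8 * sin(2 * pi * t / 168) * (1 - exp(-t / 240))
}

#' Generate a self-consistent identification record
#'
#' Simulates the plant under the given parameters, dosing schedule and TSH
#' signal and packages the result as an [ident_data()] record (noiseless by
#' default).
#'
#' @param params a [thyroid_params()] object (the "true" patient)
#' @param doses a [dose_schedule()]; default the 50/80/110 ug/day staircase
#' @param tsh TSH signal (vector or function); default [synthetic_tsh()]
#' @param days record length in days
#' @param ft4_0 initial FT4 (ng/L)
#' @param noise_sd standard deviation of additive FT4 measurement noise
#' @export
make_ident_record <- function(params, doses = staircase_schedule(),
                              tsh = synthetic_tsh, days = 90,
                              ft4_0 = 5, noise_sd = 0) {
  t_end <- days * 24
  doses <- doses[doses$time_h <= t_end, ]   # clip the schedule to the record
  traj <- simulate_plant(params, doses, tsh, t_end, x0 = c(0, ft4_0))
  dose_col <- numeric(nrow(traj))
  idx <- match(doses$time_h, traj$time_h)
  keep <- !is.na(idx)
  dose_col[idx[keep]] <- doses$dose_ug[keep]
  y <- traj$ft4
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), sd = noise_sd)
  ident_data(traj$time_h, dose_col, traj$tsh, y)
}

#' Write / read an identification record as CSV
#' (columns time_h, dose_ug, tsh_mU_L, ft4)
#' @param data an [ident_data()] record
#' @param path file path
#' @export
write_ident_data <- function(data, path) {
  out <- data.frame(time_h = data$time_h, dose_ug = data$dose_ug,
                    tsh_mU_L = data$tsh, ft4 = data$ft4)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ident_data
#' @export
read_ident_data <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_h", "dose_ug", "tsh_mU_L", "ft4")
  if (!all(need %in% names(df))) {
    stop("identification CSV must have columns time_h, dose_ug, tsh_mU_L, ft4")
  }
  ident_data(df$time_h, df$dose_ug, df$tsh_mU_L, df$ft4)
}
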
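# Shared fixtures: the nominal fitted parameter set, its controller, and a
# deSolve reference integrator used as the independent oracle for the
# closed-form propagation.

nominal_params <- function() thyroid_params()

nominal_controller <- function() {
  design_controller(discretize_impulse_invariant(thyroid_params()))
}

# Adaptive-step oracle for the two-state model under impulsive dosing and
# an arbitrary TSH signal (interpolated with a zero-order hold so that it
# matches the simulator's piecewise-constant convention exactly).
ode_oracle <- function(params, doses, tsh_vec, t_end, x0 = c(0, 0),
                       bioavailability = 1, rtol = 1e-10, atol = 1e-12) {
  skip_if_not_installed("deSolve")
  tsh_at <- stats::stepfun(seq_len(t_end), tsh_vec)
  rhs <- function(t, x, parms) {
    tsh <- tsh_at(t)
    list(c(-params$kexc * x[1],
           params$vmax * tsh / (params$km + tsh) +
             params$kreac * x[1] - params$ksec * x[2]))
  }
  ev <- NULL
  if (nrow(doses) > 0) {
    ev <- list(data = data.frame(
      var = "x1", time = doses$time_h,
      value = doses$dose_ug / LT4_MOLAR_MASS * bioavailability,
      method = "add"))
  }
  out <- deSolve::ode(c(x1 = x0[1], x2 = x0[2]), 0:t_end, rhs, NULL,
                      events = ev, rtol = rtol, atol = atol)
  data.frame(time_h = out[, 1], x1_umol = out[, 2], ft4 = out[, 3])
}

# random but physiologically plausible parameter draw
random_params <- function() {
  thyroid_params(
    kreac = stats::runif(1, 2, 20),
    km = stats::runif(1, 2e3, 2e4),
    vmax = stats::runif(1, 5e-5, 5e-4),
    kexc = stats::runif(1, 0.16, 0.36),
    ksec = log(2) / (stats::runif(1, 9, 10) * 24)
  )
}

random_schedule <- function(days, max_dose = 150) {
  daily_schedule(stats::runif(days, 0, max_dose))
}

# generic polynomial product (ascending coefficients) — oracle helper
poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}
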
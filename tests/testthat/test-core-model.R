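test_that("parameter validation enforces the model invariants", {
  expect_error(thyroid_params(kreac = -1), "positive")
  expect_error(thyroid_params(vmax = 0), "positive")
  expect_error(thyroid_params(kexc = 0.1, ksec = 0.1), "kexc must differ")
  p <- thyroid_params(kreac = 7.25, kreac_scale = "1e-6")
  expect_equal(p$kreac, 7.25e-6)
})

test_that("state-space form has the expected structure and eigenvalues", {
  for (i in 1:10) {
    p <- random_params()
    sm <- system_matrices(p)
    expect_equal(sm$A, matrix(c(-p$kexc, p$kreac, 0, -p$ksec), 2))
    expect_equal(sm$b, c(1, 0))
    expect_equal(sm$V, c(0, p$vmax))
    expect_equal(sm$cT, c(0, 1))
    expect_equal(sort(sm$eigenvalues), sort(eigen(sm$A)$values))
    expect_equal(sm$eigenvalues, c(-p$kexc, -p$ksec))
    # determinant of [b, A b] reduces to kreac, so kreac != 0 <=> controllable
    expect_equal(det(sm$controllability_matrix), p$kreac)
    expect_true(sm$controllable)
  }
})

test_that("continuous transfer functions match the state-space model", {
  p <- nominal_params()
  tf <- continuous_tf(p)
  # denominator factors as (s + kexc)(s + ksec)
  expect_equal(sort(Re(polyroot(rev(tf$G$den)))),
               sort(c(-p$kexc, -p$ksec)), tolerance = 1e-10)
  expect_equal(Re(tf_eval(tf$G, 0)), p$kreac / (p$ksec * p$kexc))
  expect_equal(Re(tf_eval(tf$S, 0)), p$vmax / p$ksec)
  # G(s) equals c' (sI - A)^{-1} b at a few probe points
  sm <- system_matrices(p)
  for (s in c(0.01, 0.1 + 0.2i, 1i)) {
    g_ss <- (sm$cT %*% solve(s * diag(2) - sm$A, sm$b))[1, 1]
    expect_equal(tf_eval(tf$G, s), g_ss, tolerance = 1e-12)
  }
})

test_that("null input gives the identically zero trajectory", {
  tr <- simulate_plant(nominal_params(), dose_schedule(), tsh = 0,
                       t_end = 200)
  expect_true(all(tr$x1_umol == 0))
  expect_true(all(tr$ft4 == 0))
})

test_that("constant-rate equilibrium follows the fixed point of the dynamics", {
  skip_if_not_installed("deSolve")
  p <- nominal_params()
  d <- 0.005; tsh <- 40
  eq <- plant_equilibrium(p, d, tsh)
  expect_equal(unname(eq["x1"]), d / p$kexc)
  expect_equal(unname(eq["x2"]),
               (p$vmax * tsh / (p$km + tsh) + p$kreac * d / p$kexc) / p$ksec)
  rhs <- function(t, x, parms) {
    list(c(d - p$kexc * x[1],
           p$vmax * tsh / (p$km + tsh) + p$kreac * x[1] - p$ksec * x[2]))
  }
  out <- deSolve::ode(c(0, 0), seq(0, 5e4, by = 100), rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(out[nrow(out), 2:3]), unname(eq), tolerance = 1e-5)
})

test_that("exact propagation matches the adaptive-step oracle on the staircase record", {
  p <- nominal_params()
  sched <- staircase_schedule()
  t_end <- 90 * 24
  tr <- simulate_plant(p, sched, synthetic_tsh, t_end, x0 = c(0, 5))
  orc <- ode_oracle(p, sched, synthetic_tsh(0:t_end), t_end, x0 = c(0, 5))
  rel <- abs(orc$ft4 - tr$ft4) / pmax(abs(orc$ft4), 1e-9)
  expect_lt(max(rel), 1e-6)
  # x1 agrees away from impulse instants (the simulator reports post-dose
  # values there, the integrator pre-dose ones)
  off_dose <- !(tr$time_h %in% sched$time_h)
  rel1 <- abs(orc$x1_umol - tr$x1_umol)[off_dose] /
    pmax(abs(orc$x1_umol), 1e-12)[off_dose]
  expect_lt(max(rel1[orc$x1_umol[off_dose] > 1e-8]), 1e-6)
})

test_that("oracle equivalence holds across random parameter and schedule draws", {
  set.seed(101)
  for (i in 1:5) {
    p <- random_params()
    sched <- random_schedule(10)
    t_end <- 10 * 24
    tsh <- 20 + 40 * stats::runif(1) * exp(-(0:t_end) / 200)
    x0 <- c(0, stats::runif(1, 0, 10))
    bio <- stats::runif(1, 0.64, 0.83)
    tr <- simulate_plant(p, sched, tsh, t_end, x0 = x0, bioavailability = bio)
    orc <- ode_oracle(p, sched, tsh, t_end, x0 = x0, bioavailability = bio)
    rel <- abs(orc$ft4 - tr$ft4) / pmax(abs(orc$ft4), 1e-9)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("positivity, superposition and dose-monotonicity hold", {
  set.seed(202)
  for (i in 1:5) {
    p <- random_params()
    t_end <- 30 * 24
    s1 <- random_schedule(30)
    s2 <- random_schedule(30)
    tsh <- stats::runif(1, 1, 80)
    tr1 <- simulate_plant(p, s1, tsh, t_end)
    tr2 <- simulate_plant(p, s2, tsh, t_end)
    expect_true(all(tr1$x1_umol >= 0))
    expect_true(all(tr1$ft4 >= 0))
    # superposition of the dose response (x1 dynamics are linear in d):
    # response to summed schedules = sum of responses minus the zero-dose
    # baseline (the endogenous term enters every run once)
    s12 <- dose_schedule(s1$time_h, s1$dose_ug + s2$dose_ug)
    tr12 <- simulate_plant(p, s12, tsh, t_end)
    tr0 <- simulate_plant(p, dose_schedule(), tsh, t_end)
    expect_equal(tr12$x1_umol, tr1$x1_umol + tr2$x1_umol, tolerance = 1e-12)
    expect_equal(tr12$ft4, tr1$ft4 + tr2$ft4 - tr0$ft4, tolerance = 1e-10)
    # increasing every dose never decreases FT4
    s_up <- dose_schedule(s1$time_h, s1$dose_ug + 10)
    tr_up <- simulate_plant(p, s_up, tsh, t_end)
    expect_true(all(tr_up$ft4 - tr1$ft4 >= -1e-12))
  }
})

test_that("invalid simulation inputs are rejected", {
  p <- nominal_params()
  expect_error(simulate_plant(p, dose_schedule(10.5, 50), 20, 100), "grid")
  expect_error(simulate_plant(p, dose_schedule(200, 50), 20, 100), "grid")
  expect_error(simulate_plant(p, dose_schedule(), -1, 100), "nonnegative")
  expect_error(simulate_plant(p, dose_schedule(), 20, 100, x0 = c(-1, 0)),
               "nonnegative")
  expect_error(dose_schedule(c(0, 0), c(10, 10)), "increasing")
  expect_error(dose_schedule(0, -5), "nonnegative")
})

test_that("trajectory and schedule CSV round-trips are lossless", {
  p <- nominal_params()
  sched <- staircase_schedule(c(50, 75), days_per_level = 2)
  tr <- simulate_plant(p, sched, 30, 4 * 24)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f1)
  expect_equal(as.data.frame(read_trajectory(f1)), as.data.frame(tr),
               tolerance = 1e-12)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_schedule(sched, f2)
  expect_equal(as.data.frame(read_schedule(f2)), as.data.frame(sched))
})
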
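test_that("the controller difference equation realises R(z)", {
  ctrl <- nominal_controller()
  s0 <- controller_state()
  # zero state, zero error -> zero output
  expect_equal(controller_step(s0, ctrl, r = 10, y = 10)$u, 0)
  # hand-unrolled recursion for errors (1, 0)
  st1 <- controller_step(s0, ctrl, r = 1, y = 0)
  expect_equal(st1$u, ctrl$b1)
  st2 <- controller_step(st1$state, ctrl, r = 0, y = 0)
  expect_equal(st2$u, ctrl$b0 - ctrl$a0 * ctrl$b1)
  # linearity: doubling state and inputs doubles the output
  stA <- controller_state(e_prev = 0.3, u_prev = -0.2)
  stB <- controller_state(e_prev = 0.6, u_prev = -0.4)
  uA <- controller_step(stA, ctrl, r = 2, y = 0.5)$u
  uB <- controller_step(stB, ctrl, r = 4, y = 1)$u
  expect_equal(uB, 2 * uA, tolerance = 1e-12)
})

test_that("dose shaping enforces rate clip, quantisation, ceiling and dead band", {
  lim <- therapy_limits()
  # rate clip then ceiling: huge command from 187.5 lands exactly at 200
  expect_equal(shape_dose(350, 187.5, lim), 200)
  expect_equal(shape_dose(1e6, 200, lim), 200)
  # dead band holds the previous dose exactly
  expect_equal(shape_dose(350, 62.5, lim, in_band = TRUE), 62.5)
  # quantised fixed point
  expect_equal(shape_dose(62.5, 62.5, lim), 62.5)
  # ties round down: halfway between quanta
  expect_equal(shape_dose(50 + 6.25, 50, lim), 50)
  expect_equal(shape_dose(50 - 6.25, 50, lim), 37.5)
  # never below zero
  expect_equal(shape_dose(-500, 0, lim), 0)
  # a max_step that is not a multiple of the quantum still bounds the change
  lim20 <- therapy_limits(max_step = 20)
  d <- shape_dose(500, 50, lim20)
  expect_lte(abs(d - 50), 20)
  expect_equal(d %% 12.5, 0)
  expect_error(therapy_limits(dose_quantum = 30, max_step = 20), "quantum")
  expect_error(therapy_limits(range_lo = 16, range_hi = 9), "range_lo")
})

test_that("the nominal run is a rising staircase that settles inside the band", {
  res <- run_closed_loop(virtual_patient(), nominal_controller())
  v <- res$visits
  expect_equal(v$dose[1], 12.5)                 # first prescription
  dd <- diff(v$dose)
  expect_true(all(abs(dd) <= 12.5 + 1e-12))     # per-visit rate bound
  expect_true(all(v$dose %% 12.5 == 0))         # tablet quantum
  expect_true(all(v$dose >= 0 & v$dose <= 200)) # safety
  # monotone ramp until the band is reached, then constant
  first_in <- which(v$in_band)[1]
  expect_true(all(dd[seq_len(first_in - 2)] == 12.5))
  expect_true(all(dd[first_in:(length(dd))] == 0))
  expect_gte(res$final_ft4, 9.2)
  expect_lte(res$final_ft4, 16)
})

test_that("a patient at its dose-matched steady state holds its dose", {
  pat <- patient_at_steady_state(virtual_patient(), 62.5)
  res <- run_closed_loop(pat, nominal_controller(), n_visits = 6,
                         initial_dose = 62.5)
  expect_true(all(res$visits$dose == 62.5))
  expect_true(all(res$visits$in_band))
})

test_that("doses step down after a reference drop until back in band", {
  # start settled high: matched to 150 ug/day the nominal patient sits above
  # the euthyroid band, and a 12 ng/L reference must walk the dose down
  pat <- patient_at_steady_state(virtual_patient(), 150)
  expect_gt(measure(pat), 16)
  res <- run_closed_loop(pat, nominal_controller(),
                         refs = reference_schedule(0, 12),
                         n_visits = 12, initial_dose = 150)
  v <- res$visits
  above <- v$ft4 > 16
  expect_true(any(above))
  expect_true(all(diff(v$dose)[above[-nrow(v)]] <= 0))  # nonincreasing while high
  expect_true(v$ft4[nrow(v)] >= 9.2 && v$ft4[nrow(v)] <= 16)
})

test_that("a refractory patient is ceiling-limited, never beyond 200 ug", {
  p_low <- thyroid_params(kreac = 7.25 / 20)
  res <- run_closed_loop(virtual_patient(p_low), nominal_controller(),
                         refs = reference_schedule(0, 16), n_visits = 20)
  expect_equal(max(res$visits$dose), 200)
  expect_true(all(res$visits$dose <= 200))
  expect_true(all(diff(res$visits$dose) <= 12.5 + 1e-12))
})

test_that("safety invariants hold across randomized patients and references", {
  set.seed(55)
  cfg <- cohort_config(n = 4, seed = 99)
  for (i in 1:4) {
    pat <- generate_patient(cfg, i)
    ref <- sample(c(10, 13, 16), 1)
    res <- run_closed_loop(pat, nominal_controller(),
                           refs = reference_schedule(0, ref), n_visits = 10)
    v <- res$visits
    expect_true(all(v$dose >= 0 & v$dose <= 200))
    expect_true(all(abs(diff(v$dose)) <= 12.5 + 1e-12))
    expect_true(all(v$dose %% 12.5 == 0))
    expect_true(all(res$hourly$ft4 >= 0))
  }
})

test_that("visit and hourly logs can be written as CSV", {
  res <- run_closed_loop(virtual_patient(), nominal_controller(),
                         n_visits = 2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_simulation_result(res, f1, f2)
  expect_equal(nrow(utils::read.csv(f1)), 2)
  expect_equal(nrow(utils::read.csv(f2)), 2 * 672)
})
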
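# The discrete-time dosing loop: controller difference equation, hard
# per-visit rate clip, 12.5 ug quantisation, the 200 ug/day ceiling, and a
# euthyroid dead band implementing the steady-state requirement (the dose
# holds while the measured FT4 sits inside the reference band and the
# reference has not moved).

#' Therapy limits
#'
#' @param dose_max daily dose ceiling (ug/day); doses above it require a
#'   physician and are never prescribed automatically
#' @param dose_quantum tablet quantum (ug); every prescribed dose is an
#'   integer multiple
#' @param max_step per-visit change bound (ug), typically 12.5-25
#' @param range_lo,range_hi euthyroid FT4 band (ng/L)
#' @export
therapy_limits <- function(dose_max = 200, dose_quantum = 12.5,
                           max_step = 12.5, range_lo = 9.2, range_hi = 16) {
  if (!(dose_quantum > 0 && dose_quantum <= max_step && max_step <= dose_max)) {
    stop("need 0 < dose_quantum <= max_step <= dose_max")
  }
  if (range_lo >= range_hi) stop("range_lo must be below range_hi")
  structure(list(dose_max = dose_max, dose_quantum = dose_quantum,
                 max_step = max_step, range_lo = range_lo,
                 range_hi = range_hi),
            class = "therapy_limits")
}

#' Piecewise-constant reference FT4 schedule
#'
#' @param time_h switch times in hours from therapy start (first must be 0)
#' @param value reference FT4 at and after each switch time (ng/L)
#' @export
reference_schedule <- function(time_h = 0, value = 13) {
  if (length(time_h) != length(value)) stop("time_h and value lengths differ")
  if (time_h[1] != 0) stop("the reference must be defined from time 0")
  if (length(time_h) > 1 && any(diff(time_h) <= 0)) {
    stop("switch times must be strictly increasing")
  }
  structure(data.frame(time_h = time_h, value = value),
            class = c("reference_schedule", "data.frame"))
}

reference_at <- function(refs, t) {
  refs$value[findInterval(t, refs$time_h)]
}

#' One step of the controller difference equation
#'
#' Realises `R(z) = (b1 z + b0)/(z + a0)` (normalised `a1 = 1`) as
#' `u_k = b1 e_k + b0 e_{k-1} - a0 u_{k-1}` with `e_k = r - y`.
#'
#' @param state list with `e_prev` and `u_prev` (zeros at therapy start);
#'   use [controller_state()] to create one
#' @param ctrl a [design_controller()] controller
#' @param r reference FT4 (ng/L)
#' @param y measured FT4 (ng/L)
#' @return list with the raw output `u` and the updated `state`
#' @export
controller_step <- function(state, ctrl, r, y) {
  if (ctrl$a1 != 1) stop("controller must be normalised to a1 = 1")
  e <- r - y
  u <- ctrl$b1 * e + ctrl$b0 * state$e_prev - ctrl$a0 * state$u_prev
  list(u = u, state = controller_state(e_prev = e, u_prev = u))
}

#' @rdname controller_step
#' @param e_prev,u_prev stored previous error and raw output
#' @export
controller_state <- function(e_prev = 0, u_prev = 0) {
  list(e_prev = e_prev, u_prev = u_prev)
}

quantize_dose <- function(x, quantum) {
  # nearest multiple, ties rounded down
  quantum * ceiling(x / quantum - 0.5)
}

#' Shape a raw controller output into a prescribable dose
#'
#' Outside the dead band the raw command is clipped to within `max_step` of
#' the previous dose, quantised to the tablet quantum (ties rounded down),
#' and clamped to `[0, dose_max]`; the per-visit change never exceeds
#' `max_step`.  Inside the dead band (`in_band = TRUE`: measured FT4 within
#' the euthyroid range and an unchanged reference) the previous dose is
#' held, which realises the steady-state requirement for a non-integrating
#' loop that would otherwise chatter through the quantiser.
#'
#' @param u raw controller output (ug/day)
#' @param prev_dose previously prescribed dose (ug/day, quantised)
#' @param limits a [therapy_limits()] object
#' @param in_band dead-band flag
#' @return prescribed dose (ug/day)
#' @export
shape_dose <- function(u, prev_dose, limits, in_band = FALSE) {
  if (in_band) return(prev_dose)
  q <- limits$dose_quantum
  step_q <- q * floor(limits$max_step / q)   # largest admissible quantised step
  d <- min(max(u, prev_dose - limits$max_step), prev_dose + limits$max_step)
  d <- quantize_dose(d, q)
  delta <- d - prev_dose
  delta <- sign(delta) * min(abs(delta), step_q)
  min(max(prev_dose + delta, 0), limits$dose_max)
}

#' Run the closed dosing loop against a patient simulator
#'
#' At each visit the patient's FT4 is measured (24-h mean of the hourly
#' output), the controller difference equation is advanced, the raw command
#' is converted from model dose units (umol/day) to micrograms and shaped by
#' the therapy limits, and the prescribed dose is held constant daily until
#' the next visit.
#'
#' @param patient an object exposing `measure()` and `advance()` methods
#'   (see [virtual_patient()])
#' @param ctrl a [design_controller()] controller
#' @param refs a [reference_schedule()]
#' @param limits a [therapy_limits()]
#' @param n_visits number of visits (months at the default `Td`)
#' @param Td visit interval in hours
#' @param initial_dose dose (ug/day) in force before the first visit
#'   (0 at therapy start)
#' @param u_scale conversion from raw controller output to ug/day; the
#'   default `LT4_MOLAR_MASS / 0.83` maps the controller's umol/day command
#'   back through the molar mass and the nominal oral bioavailability
#' @return object of class `simulation_result`: per-visit records
#'   (`visits`), the hourly FT4/TSH log (`hourly`), the daily dose series,
#'   and `final_ft4` (24-h mean after the last month)
#' @export
run_closed_loop <- function(patient, ctrl, refs = reference_schedule(),
                            limits = therapy_limits(), n_visits = 12,
                            Td = ctrl$Td, initial_dose = 0,
                            u_scale = LT4_MOLAR_MASS / 0.83) {
  stopifnot(inherits(ctrl, "controller_tf"))
  state <- controller_state()
  prev_dose <- initial_dose
  r_prev <- NA_real_
  visits <- vector("list", n_visits)
  hourly <- vector("list", n_visits)
  doses_daily <- numeric(0)

  for (k in seq_len(n_visits)) {
    t_k <- (k - 1) * Td
    y <- measure(patient)
    r <- reference_at(refs, t_k)
    # the reference counts as unchanged at the first visit (it has been in
    # force since t = 0), so a patient already in band holds its dose
    in_band <- y >= limits$range_lo && y <= limits$range_hi &&
      (is.na(r_prev) || r == r_prev)
    cs <- controller_step(state, ctrl, r, y)
    state <- cs$state
    u_ug <- cs$u * u_scale
    dose <- shape_dose(u_ug, prev_dose, limits, in_band)
    visits[[k]] <- data.frame(visit = k, time_h = t_k, ft4 = y, ref = r,
                              u_raw_ug = u_ug, dose = dose,
                              in_band = in_band)
    adv <- advance(patient, dose_ug = dose, hours = Td)
    patient <- adv$patient
    hourly[[k]] <- adv$hourly
    doses_daily <- c(doses_daily, rep(dose, Td / 24))
    prev_dose <- dose
    r_prev <- r
  }
  structure(list(
    visits = do.call(rbind, visits),
    hourly = do.call(rbind, hourly),
    doses_daily = doses_daily,
    final_ft4 = measure(patient),
    patient = patient
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  v <- x$visits
  cat(sprintf("closed-loop dosing run: %d visits\n", nrow(v)))
  cat(sprintf("  doses: first %.1f, last %.1f, max %.1f ug/day\n",
              v$dose[1], v$dose[nrow(v)], max(v$dose)))
  cat(sprintf("  FT4: first measured %.2f, final %.2f ng/L\n",
              v$ft4[1], x$final_ft4))
  invisible(x)
}

#' Write the per-visit and hourly records of a run as CSV
#' @param result a [run_closed_loop()] result
#' @param visits_csv,hourly_csv output paths (NULL to skip)
#' @export
write_simulation_result <- function(result, visits_csv = NULL,
                                    hourly_csv = NULL) {
  if (!is.null(visits_csv)) {
    utils::write.csv(result$visits, visits_csv, row.names = FALSE)
  }
  if (!is.null(hourly_csv)) {
    utils::write.csv(result$hourly, hourly_csv, row.names = FALSE)
  }
  invisible(result)
}
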
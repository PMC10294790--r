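# Discrete-time controller synthesis: impulse-invariant discretization of
# the plant, the first-order rate limiter, and pole placement through the
# Diophantine identity a(z) v(z) + b(z) mu(z) = vT(z).

#' Controller design settings
#'
#' @param z0 desired (triple) closed-loop pole; must satisfy `|z0| < 1`.
#'   The default -0.01 keeps the loop fast but overshoot-free.
#' @param Td sampling (visit) interval in hours; default 672 h = 28 days
#' @param kr rate-limiter smoothing gain in (0, 1]
#' @param neglect_threshold bound under which the q1*q2 product of the
#'   second-order discretization is dropped (reduced first-order plant)
#' @export
design_spec <- function(z0 = -0.01, Td = 672, kr = 0.5,
                        neglect_threshold = 1e-6) {
  if (abs(z0) >= 1) stop("the desired pole z0 must lie inside the unit circle")
  if (Td <= 0) stop("Td must be positive")
  if (kr <= 0 || kr > 1) stop("kr must lie in (0, 1]")
  structure(list(z0 = z0, Td = Td, kr = kr,
                 neglect_threshold = neglect_threshold),
            class = "design_spec")
}

#' Impulse-invariant discretization of the plant
#'
#' With `A = kreac/(ksec - kexc)`, `q1 = exp(-ksec Td)`, `q2 = exp(-kexc Td)`
#' the sampled plant is `G(z) = A (q2 - q1) z / (z^2 - (q1+q2) z + q1 q2)`.
#' For visit-scale sampling times the product `q1 q2` is negligible and the
#' reduced first-order form `G(z) = A p1 / (z - p2)` with `p1 = q2 - q1`,
#' `p2 = q1 + q2` is used for the design (note that with `ksec < kexc` both
#' `A` and `p1` are negative, so the effective gain `A p1` is positive).
#'
#' @param params a [thyroid_params()] object
#' @param Td sampling time in hours
#' @param threshold neglect threshold for `q1*q2`
#' @return object of class `discrete_plant` with fields `A_gain`, `q1`,
#'   `q2`, `p1`, `p2`, `Td`, `reduced`
#' @export
discretize_impulse_invariant <- function(params, Td = 672, threshold = 1e-6) {
  stopifnot(inherits(params, "thyroid_params"))
  if (Td <= 0) stop("Td must be positive")
  q1 <- exp(-params$ksec * Td)
  q2 <- exp(-params$kexc * Td)
  A <- params$kreac / (params$ksec - params$kexc)
  reduced <- q1 * q2 < threshold
  if (!reduced) {
    warning("q1*q2 = ", format(q1 * q2),
            " is not negligible at this sampling time; ",
            "the full second-order form is retained and the reduced-form ",
            "design path is unavailable")
  }
  structure(list(A_gain = A, q1 = q1, q2 = q2,
                 p1 = q2 - q1, p2 = q1 + q2,
                 Td = Td, threshold = threshold, reduced = reduced),
            class = "discrete_plant")
}

#' @export
print.discrete_plant <- function(x, ...) {
  cat(sprintf("impulse-invariant discrete plant (Td = %g h)\n", x$Td))
  cat(sprintf("  A = %.6g, q1 = %.6g, q2 = %.6g\n", x$A_gain, x$q1, x$q2))
  cat(sprintf("  reduced form G(z) = A p1 / (z - p2): %s (q1*q2 = %.3g)\n",
              if (x$reduced) "active" else "NOT active", x$q1 * x$q2))
  invisible(x)
}

#' First-order rate limiter
#'
#' Open-loop block `Kr(z) = kr/(z - 1)` closed under unity feedback gives
#' `Krz(z) = kr/(z - Delta)` with `Delta = 1 - kr`, i.e. the recursion
#' `y[k+1] = Delta*y[k] + kr*u[k]` — a unit-DC-gain smoother whose step
#' response starts at `kr` and approaches the input geometrically.
#'
#' @param kr limiter gain in (0, 1]
#' @return list with `kr`, `Delta`, the transfer functions `Kr` and `Krz`,
#'   and `step(u, y0)` applying the recursion to an input sequence
#' @export
rate_limiter <- function(kr) {
  if (kr <= 0 || kr > 1) stop("kr must lie in (0, 1]")
  Delta <- 1 - kr
  list(
    kr = kr, Delta = Delta,
    Kr = rational_tf(kr, c(1, -1), "z"),
    Krz = rational_tf(kr, c(1, -Delta), "z"),
    step = function(u, y0 = 0) {
      as.numeric(stats::filter(kr * u, Delta, method = "recursive", init = y0))
    }
  )
}

#' Rate-limited total plant for controller design
#'
#' `Gp(z) = Krz(z) G(z) = mu0 / (z^2 + v1 z + v0)` with `mu0 = A p1 kr`,
#' `v1 = -(p2 + Delta)`, `v0 = p2 Delta`.
#'
#' @param plant a reduced [discretize_impulse_invariant()] plant
#' @param kr rate-limiter gain
#' @export
total_plant <- function(plant, kr) {
  stopifnot(inherits(plant, "discrete_plant"))
  if (!plant$reduced) {
    stop("the design path requires the reduced first-order plant form")
  }
  Delta <- 1 - kr
  mu0 <- plant$A_gain * plant$p1 * kr
  if (mu0 == 0) stop("plant gain zero / pole placement impossible")
  list(mu0 = mu0, mu1 = 0,
       v1 = -(plant$p2 + Delta), v0 = plant$p2 * Delta,
       kr = kr, Delta = Delta,
       Gp = rational_tf(mu0, c(1, -(plant$p2 + Delta), plant$p2 * Delta), "z"))
}

#' Pole-placement design of the first-order dose controller
#'
#' Solves `a(z) v(z) + b(z) mu(z) = vT(z)` for
#' `R(z) = (b1 z + b0)/(a1 z + a0)` with the monic target
#' `vT(z) = (z - z0)^3`, placing all closed-loop poles of the rate-limited
#' loop at `z0`.  With `a1 = 1` the coefficients follow by matching:
#' `a0 = w2 - v1`, `b1 = (w1 - v0 - a0 v1)/mu0`, `b0 = (w0 - a0 v0)/mu0`.
#'
#' @param plant a reduced [discretize_impulse_invariant()] plant
#' @param spec a [design_spec()]
#' @return object of class `controller_tf` with fields `b1`, `b0`, `a1`,
#'   `a0` plus the design metadata (`z0`, `Td`, `kr`, `mu0`, `v1`, `v0`)
#' @export
design_controller <- function(plant, spec = design_spec()) {
  stopifnot(inherits(plant, "discrete_plant"), inherits(spec, "design_spec"))
  tp <- total_plant(plant, spec$kr)
  z0 <- spec$z0
  # vT(z) = (z - z0)^3 = z^3 + w2 z^2 + w1 z + w0
  w2 <- -3 * z0
  w1 <- 3 * z0^2
  w0 <- -z0^3
  a1 <- 1
  a0 <- w2 - tp$v1
  b1 <- (w1 - tp$v0 - a0 * tp$v1) / tp$mu0
  b0 <- (w0 - a0 * tp$v0) / tp$mu0
  structure(list(b1 = b1, b0 = b0, a1 = a1, a0 = a0,
                 z0 = z0, Td = plant$Td, kr = spec$kr,
                 mu0 = tp$mu0, v1 = tp$v1, v0 = tp$v0),
            class = "controller_tf")
}

#' @export
print.controller_tf <- function(x, ...) {
  cat("discrete dose controller R(z) = (b1 z + b0)/(z + a0)\n")
  cat(sprintf("  b1 = %.6g, b0 = %.6g, a0 = %.6g\n", x$b1, x$b0, x$a0))
  cat(sprintf("  designed for z0 = %g (triple), Td = %g h, kr = %g\n",
              x$z0, x$Td, x$kr))
  invisible(x)
}

#' Serialize / load a controller and its design plant as JSON
#' @param ctrl a [design_controller()] result
#' @param path file path
#' @export
write_controller <- function(ctrl, path) {
  jsonlite::write_json(unclass(ctrl), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_controller
#' @export
read_controller <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("b1", "b0", "a1", "a0", "z0", "Td", "kr", "mu0", "v1", "v0")
  if (!all(need %in% names(obj))) stop("controller JSON is missing fields")
  structure(obj[need], class = "controller_tf")
}
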
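# Plant constants and basic linear-systems views of the two-state model.

#' Molar mass of levothyroxine sodium-free T4 (g/mol), used to convert
#' prescribed micrograms to the micromole dose input of the model.
#' @export
LT4_MOLAR_MASS <- 776.87

#' Nominal rate constants
#'
#' The oral-compartment elimination rate defaults to 0.26 1/h (the centre of
#' the robustness interval used for controller verification) and the natural
#' FT4 elimination rate to ln(2)/(9.5 days), the midpoint of the 9-10 day
#' T4 half-life reported for hypothyroid patients.
#' @name nominal-rates
#' @export
KEXC_NOMINAL <- 0.26

#' @rdname nominal-rates
#' @export
KSEC_NOMINAL <- log(2) / (9.5 * 24)

#' Plant parameter set
#'
#' Bundles the five constants of the two-state model of FT4 dynamics under
#' oral LT4: an exogenous-T4 compartment `x1` (umol) filled by impulsive
#' daily doses and drained at rate `kexc`, and the FT4 state `x2` (ng/L)
#' driven by `kreac * x1` plus Michaelis-Menten endogenous production
#' `vmax * TSH / (km + TSH)` and drained at rate `ksec`.
#'
#' @param kreac gain from the exogenous compartment to FT4 ("ppm"; treated
#'   as a raw multiplicative factor by default, see `kreac_scale`)
#' @param km Michaelis constant of the TSH-driven production term (umol)
#' @param vmax maximum endogenous production rate (umol/h)
#' @param kexc elimination rate of the oral LT4 compartment (1/h)
#' @param ksec natural FT4 elimination rate (1/h)
#' @param kreac_scale either `"raw"` (default: `kreac` enters the dynamics
#'   as printed) or `"1e-6"` (a literal parts-per-million reading)
#' @return an object of class `thyroid_params`
#' @export
thyroid_params <- function(kreac = 7.25, km = 9.504e3, vmax = 2.19e-4,
                           kexc = KEXC_NOMINAL, ksec = KSEC_NOMINAL,
                           kreac_scale = c("raw", "1e-6")) {
  kreac_scale <- match.arg(kreac_scale)
  vals <- c(kexc = kexc, ksec = ksec, vmax = vmax, km = km, kreac = kreac)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all plant constants must be finite and strictly positive")
  }
  if (kexc == ksec) {
    stop("kexc must differ from ksec (discretization gain A = kreac/(ksec - kexc))")
  }
  if (kreac_scale == "1e-6") kreac <- kreac * 1e-6
  structure(
    list(kexc = kexc, ksec = ksec, vmax = vmax, km = km, kreac = kreac,
         kreac_scale = kreac_scale),
    class = "thyroid_params"
  )
}

#' @export
print.thyroid_params <- function(x, ...) {
  cat("Two-state LT4/FT4 plant parameters\n")
  cat(sprintf("  kexc  = %.4g 1/h   (oral-compartment elimination)\n", x$kexc))
  cat(sprintf("  ksec  = %.4g 1/h   (FT4 elimination, half-life %.2f days)\n",
              x$ksec, log(2) / x$ksec / 24))
  cat(sprintf("  vmax  = %.4g umol/h\n", x$vmax))
  cat(sprintf("  km    = %.4g umol\n", x$km))
  cat(sprintf("  kreac = %.4g (%s)\n", x$kreac, x$kreac_scale))
  invisible(x)
}

#' State-space form of the plant
#'
#' Returns the matrices of `dx/dt = A x + b d + V p`, `y = c' x` with
#' disturbance `p = TSH/(km + TSH)`, together with the eigenvalues
#' (`-kexc`, `-ksec`) and a controllability flag (the determinant of the
#' controllability matrix `[b, A b]` reduces to `kreac`).
#'
#' @param params a [thyroid_params()] object
#' @return list with `A`, `b`, `V`, `cT`, `eigenvalues`, `controllable`
#' @export
system_matrices <- function(params) {
  stopifnot(inherits(params, "thyroid_params"))
  A <- matrix(c(-params$kexc, params$kreac, 0, -params$ksec), nrow = 2)
  b <- c(1, 0)
  V <- c(0, params$vmax)
  cT <- c(0, 1)
  ctrb <- cbind(b, A %*% b)
  list(
    A = A, b = b, V = V, cT = cT,
    eigenvalues = c(-params$kexc, -params$ksec),
    controllability_matrix = ctrb,
    controllable = det(ctrb) != 0
  )
}

#' Rational transfer function container
#'
#' @param num,den numerator / denominator coefficients in descending powers
#' @param domain `"s"` (continuous) or `"z"` (discrete)
#' @export
rational_tf <- function(num, den, domain = c("s", "z")) {
  domain <- match.arg(domain)
  num <- as.numeric(num); den <- as.numeric(den)
  if (length(den) < 1L || den[1] == 0) {
    stop("denominator leading coefficient must be nonzero")
  }
  structure(list(num = num, den = den, domain = domain), class = "rational_tf")
}

#' @export
print.rational_tf <- function(x, ...) {
  fmt <- function(cf) paste(sprintf("%.6g", cf), collapse = ", ")
  cat(sprintf("rational transfer function in %s\n", x$domain))
  cat("  num (descending):", fmt(x$num), "\n")
  cat("  den (descending):", fmt(x$den), "\n")
  invisible(x)
}

#' Evaluate a rational transfer function
#' @param tf a [rational_tf()] object
#' @param x point(s) in the s- or z-plane (may be complex)
#' @export
tf_eval <- function(tf, x) {
  horner <- function(cf, x) {
    acc <- rep(cf[1] + 0i * x, length.out = length(x)) * 0 + cf[1]
    for (c_i in cf[-1]) acc <- acc * x + c_i
    acc
  }
  horner(tf$num, x) / horner(tf$den, x)
}

#' Continuous-time transfer functions of the plant
#'
#' `G(s) = kreac / (s^2 + (ksec + kexc) s + ksec kexc)` from the dose input
#' and `S(s) = vmax / (s + ksec)` from the TSH disturbance `p` to the FT4
#' output.
#'
#' @param params a [thyroid_params()] object
#' @return list with elements `G` and `S`, both [rational_tf()] in `s`
#' @export
continuous_tf <- function(params) {
  stopifnot(inherits(params, "thyroid_params"))
  list(
    G = rational_tf(params$kreac,
                    c(1, params$ksec + params$kexc, params$ksec * params$kexc),
                    "s"),
    S = rational_tf(params$vmax, c(1, params$ksec), "s")
  )
}
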
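# Robust Schur stability of the closed dosing loop over the kexc
# uncertainty interval, via the four Jury-Pavlidis conditions for a
# continuously parameterised polynomial family.
#
# Polynomials are plain numeric vectors of coefficients in ASCENDING powers
# (a0, a1, ..., an) with a nonzero leading coefficient.

poly_degree <- function(p) length(p) - 1L

poly_eval <- function(p, z) {
  acc <- 0 * z + p[length(p)]
  for (k in rev(seq_len(length(p) - 1L))) acc <- acc * z + p[k]
  acc
}

#' Closed-loop characteristic polynomial at a given parameter point
#'
#' Re-evaluates the reduced discrete plant (`A`, `p1`, `p2`) at the supplied
#' rates and expands `a(z) v(z) + b(z) mu(z)` for the fixed controller,
#' yielding the cubic (ascending coefficients)
#' `[a0 p2 D + b0 A p1 kr,  a1 p2 D - a0 (p2 + D) + A p1 kr b1,
#'   a0 - a1 (p2 + D),  a1]` with `D = 1 - kr`.
#'
#' @param ctrl a [design_controller()] controller
#' @param params a [thyroid_params()] object giving the plant at this point
#'   (typically the nominal set with a perturbed `kexc`)
#' @param Td sampling time in hours (defaults to the controller's)
#' @param kr rate-limiter gain (defaults to the controller's)
#' @return numeric vector of ascending coefficients, degree 3
#' @export
closed_loop_charpoly <- function(ctrl, params, Td = ctrl$Td, kr = ctrl$kr) {
  stopifnot(inherits(ctrl, "controller_tf"), inherits(params, "thyroid_params"))
  q1 <- exp(-params$ksec * Td)
  q2 <- exp(-params$kexc * Td)
  A <- params$kreac / (params$ksec - params$kexc)
  p1 <- q2 - q1
  p2 <- q1 + q2
  D <- 1 - kr
  g <- A * p1 * kr
  c(ctrl$a0 * p2 * D + ctrl$b0 * g,
    ctrl$a1 * p2 * D - ctrl$a0 * (p2 + D) + g * ctrl$b1,
    ctrl$a0 - ctrl$a1 * (p2 + D),
    ctrl$a1)
}

#' Jury-Pavlidis X and Y matrices
#'
#' For a degree-n polynomial `a0 + a1 z + ... + an z^n` builds the
#' `(n-1) x (n-1)` matrices `X` (upper-triangular band of leading
#' coefficients, `X[i,j] = a_{n-j+i}`) and `Y` (lower band of trailing
#' coefficients, `Y[i,j] = a_{i+j-n}`); for a cubic these are
#' `X = [[a3, a2], [0, a3]]` and `Y = [[0, a0], [a0, a1]]`.
#'
#' @param p polynomial coefficients in ascending powers, degree >= 2
#' @return list with matrices `X` and `Y`
#' @export
jury_matrices <- function(p) {
  n <- poly_degree(p)
  if (n < 2) stop("the Jury-Pavlidis matrices require degree >= 2")
  if (p[n + 1L] == 0) stop("leading coefficient must be nonzero")
  a <- function(k) {
    out <- numeric(length(k))
    ok <- k >= 0 & k <= n
    out[ok] <- p[k[ok] + 1L]
    out
  }
  idx <- seq_len(n - 1L)
  X <- outer(idx, idx, function(i, j) a(n - j + i))
  Y <- outer(idx, idx, function(i, j) a(i + j - n))
  list(X = X, Y = Y)
}

#' Schur stability of a single polynomial
#'
#' TRUE iff every root lies strictly inside the unit circle.  Roots are
#' computed as eigenvalues of the companion matrix of the monic-normalised
#' polynomial.
#'
#' @param p polynomial coefficients in ascending powers
#' @export
is_schur <- function(p) {
  n <- poly_degree(p)
  if (n < 1) return(TRUE)           # nonzero constants have no roots
  monic <- p / p[n + 1L]
  if (n == 1) return(abs(-monic[1]) < 1)
  C <- matrix(0, n, n)
  C[cbind(2:n, 1:(n - 1L))] <- 1
  C[, n] <- -monic[1:n]
  all(Mod(eigen(C, only.values = TRUE)$values) < 1)
}

#' Parameterised polynomial family
#'
#' @param fun function mapping the uncertain parameter `q` to ascending
#'   polynomial coefficients
#' @param q_range interval `c(q_min, q_max)` of the uncertain parameter
#' @param q0 nominal parameter value (inside the interval)
#' @export
poly_family <- function(fun, q_range, q0 = mean(q_range)) {
  if (length(q_range) != 2 || q_range[1] >= q_range[2]) {
    stop("q_range must be a nondegenerate interval c(q_min, q_max)")
  }
  if (q0 < q_range[1] || q0 > q_range[2]) stop("q0 must lie inside q_range")
  structure(list(fun = fun, q_range = q_range, q0 = q0),
            class = "poly_family")
}

#' Characteristic-polynomial family over the kexc interval
#'
#' The single-parameter family used for robustness verification: the
#' controller is held fixed while the oral-elimination rate sweeps its
#' uncertainty interval (all other plant constants stay nominal).
#'
#' @param ctrl a [design_controller()] controller
#' @param params nominal [thyroid_params()]
#' @param kexc_range uncertainty interval for `kexc` (1/h)
#' @param Td,kr loop constants (default from the controller)
#' @export
charpoly_family <- function(ctrl, params, kexc_range = c(0.16, 0.36),
                            Td = ctrl$Td, kr = ctrl$kr) {
  fun <- function(q) {
    pq <- thyroid_params(kreac = params$kreac, km = params$km,
                         vmax = params$vmax, kexc = q, ksec = params$ksec)
    closed_loop_charpoly(ctrl, pq, Td = Td, kr = kr)
  }
  q0 <- params$kexc
  if (q0 < kexc_range[1] || q0 > kexc_range[2]) q0 <- mean(kexc_range)
  poly_family(fun, kexc_range, q0 = q0)
}

#' Jury-Pavlidis robust-stability check of a polynomial family
#'
#' Evaluates the four conditions on a grid over the parameter interval:
#' (i) the nominal member is Schur; (ii) `p(1, q) != 0`; (iii)
#' `p(-1, q) != 0`; (iv) `det(X(q) - Y(q)) != 0`.  "Nonzero" uses the
#' relative tolerance `|v| > 1e-12 (1 + max|coefficient|)` and additionally
#' fails on any sign change between adjacent grid points (a sign change
#' implies a zero crossing of the continuous trace).
#'
#' @param family a [poly_family()]
#' @param grid_size number of grid points (>= 2)
#' @return object of class `stability_report`: condition flags, the grid
#'   traces (`q`, `p1`, `pm1`, `detS`, `schur`), and the overall `verdict`
#' @export
family_stability_check <- function(family, grid_size = 1001) {
  stopifnot(inherits(family, "poly_family"))
  if (grid_size < 2) stop("grid_size must be at least 2")
  qs <- seq(family$q_range[1], family$q_range[2], length.out = grid_size)
  polys <- lapply(qs, family$fun)
  coef_max <- max(vapply(polys, function(p) max(abs(p)), numeric(1)))
  tol <- 1e-12 * (1 + coef_max)

  p1 <- vapply(polys, poly_eval, numeric(1), z = 1)
  pm1 <- vapply(polys, poly_eval, numeric(1), z = -1)
  detS <- vapply(polys, function(p) {
    m <- jury_matrices(p)
    det(m$X - m$Y)
  }, numeric(1))
  schur <- vapply(polys, is_schur, logical(1))

  nonzero <- function(v) all(abs(v) > tol) && all(diff(sign(v)) == 0)
  cond <- c(
    i = is_schur(family$fun(family$q0)),
    ii = nonzero(p1),
    iii = nonzero(pm1),
    iv = nonzero(detS)
  )
  structure(list(
    conditions = cond,
    verdict = all(cond),
    q0 = family$q0,
    traces = data.frame(q = qs, p1 = p1, pm1 = pm1, detS = detS,
                        schur = schur)
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Jury-Pavlidis robust-stability report\n")
  cat(sprintf("  interval: [%g, %g], nominal q0 = %g, grid %d points\n",
              min(x$traces$q), max(x$traces$q), x$q0, nrow(x$traces)))
  lab <- c(i = "nominal member Schur", ii = "p(1, q) != 0",
           iii = "p(-1, q) != 0", iv = "det(X - Y) != 0")
  for (k in names(lab)) {
    cat(sprintf("  (%s) %-22s %s\n", k, lab[[k]],
                if (x$conditions[[k]]) "PASS" else "FAIL"))
  }
  cat(sprintf("  verdict: %s\n",
              if (x$verdict) "robustly Schur-stable" else "NOT verified"))
  invisible(x)
}

#' Certified stability interval on a parameter grid
#'
#' Sweeps the closed-loop characteristic polynomial over a `kexc` grid,
#' applies the pointwise Jury-Pavlidis conditions (`p(1) != 0`,
#' `p(-1) != 0`, `det(X - Y) != 0`) at every point, requires the nominal
#' member to be Schur, and returns the maximal contiguous passing interval
#' containing the nominal value — the certified robust-stability region.
#'
#' @param ctrl a [design_controller()] controller
#' @param params nominal [thyroid_params()] (its `kexc` anchors the interval)
#' @param kexc_grid grid of `kexc` values to test
#' @return list with `pass` (logical per grid point), `lower`, `upper`
#'   (certified interval bounds) and the `grid`
#' @export
stability_margin <- function(ctrl, params,
                             kexc_grid = seq(0.10, 0.50, by = 0.005)) {
  polys <- lapply(kexc_grid, function(q) {
    pq <- thyroid_params(kreac = params$kreac, km = params$km,
                         vmax = params$vmax, kexc = q, ksec = params$ksec)
    closed_loop_charpoly(ctrl, pq)
  })
  coef_max <- max(vapply(polys, function(p) max(abs(p)), numeric(1)))
  tol <- 1e-12 * (1 + coef_max)
  pass <- vapply(polys, function(p) {
    m <- jury_matrices(p)
    abs(poly_eval(p, 1)) > tol && abs(poly_eval(p, -1)) > tol &&
      abs(det(m$X - m$Y)) > tol
  }, logical(1))
  i0 <- which.min(abs(kexc_grid - params$kexc))
  if (!pass[i0] || !is_schur(polys[[i0]])) {
    return(list(pass = pass, lower = NA_real_, upper = NA_real_,
                grid = kexc_grid))
  }
  hi <- i0
  while (hi < length(kexc_grid) && pass[hi + 1L]) hi <- hi + 1L
  lo <- i0
  while (lo > 1L && pass[lo - 1L]) lo <- lo - 1L
  list(pass = pass, lower = kexc_grid[lo], upper = kexc_grid[hi],
       grid = kexc_grid)
}

#' Serialize a stability report as JSON (plus optional CSV of grid traces)
#' @param report a [family_stability_check()] report
#' @param path JSON path
#' @param traces_csv optional CSV path for the grid traces
#' @export
write_stability_report <- function(report, path, traces_csv = NULL) {
  out <- list(conditions = as.list(report$conditions),
              verdict = report$verdict, q0 = report$q0,
              q_min = min(report$traces$q), q_max = max(report$traces$q),
              grid_size = nrow(report$traces))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(traces_csv)) {
    utils::write.csv(report$traces, traces_csv, row.names = FALSE)
  }
  invisible(path)
}
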
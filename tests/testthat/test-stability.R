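test_that("the closed-loop characteristic polynomial hits the design target", {
  p <- nominal_params()
  ctrl <- nominal_controller()
  cp <- closed_loop_charpoly(ctrl, p)
  # by construction of pole placement: (z + 0.01)^3
  vT <- poly_mult(poly_mult(c(0.01, 1), c(0.01, 1)), c(0.01, 1))
  expect_equal(cp, vT, tolerance = 1e-10)
  # a triple root is ill-conditioned (~eps^(1/3)); the coefficient identity
  # above is the sharp check, the root locations are confirmatory
  expect_lt(max(abs(polyroot(cp) + 0.01)), 5e-6)
})

test_that("the characteristic polynomial matches a symbolic expansion oracle", {
  p <- nominal_params()
  ctrl <- nominal_controller()
  for (kexc in c(0.16, 0.2, 0.36)) {
    pq <- thyroid_params(kexc = kexc)
    cp <- closed_loop_charpoly(ctrl, pq)
    # independent path: rebuild v(z), mu(z) at this kexc and multiply out
    dq <- discretize_impulse_invariant(pq, ctrl$Td)
    Delta <- 1 - ctrl$kr
    v <- c(dq$p2 * Delta, -(dq$p2 + Delta), 1)
    mu0 <- dq$A_gain * dq$p1 * ctrl$kr
    oracle <- poly_mult(c(ctrl$a0, ctrl$a1), v) +
      c(ctrl$b0 * mu0, ctrl$b1 * mu0, 0, 0)
    expect_equal(cp, oracle, tolerance = 1e-12)
  }
  # coefficients vary continuously in kexc (finite differences stay small)
  grid <- seq(0.16, 0.36, length.out = 200)
  coefs <- sapply(grid, function(q) {
    closed_loop_charpoly(ctrl, thyroid_params(kexc = q))
  })
  expect_lt(max(abs(t(diff(t(coefs))))), 0.1)
})

test_that("Jury-Pavlidis matrices follow the displayed pattern", {
  # cubic a0 + a1 z + a2 z^2 + a3 z^3
  a <- c(2, 3, 5, 7)
  m <- jury_matrices(a)
  expect_equal(m$X, matrix(c(7, 0, 5, 7), 2))
  expect_equal(m$Y, matrix(c(0, 2, 2, 3), 2))
  # closed-form determinant for a cubic: a3(a3 - a1) + a0(a2 - a0)
  set.seed(21)
  for (i in 1:20) {
    a <- stats::rnorm(4); a[4] <- a[4] + sign(a[4]) + 0.1
    m <- jury_matrices(a)
    expect_equal(det(m$X - m$Y),
                 a[4] * (a[4] - a[2]) + a[1] * (a[3] - a[1]),
                 tolerance = 1e-12)
  }
  # z^3: det(X - Y) = 1
  m3 <- jury_matrices(c(0, 0, 0, 1))
  expect_equal(det(m3$X - m3$Y), 1)
  # degree 4: brute-force pattern-following oracle
  for (i in 1:10) {
    a <- stats::rnorm(5); a[5] <- a[5] + sign(a[5]) + 0.1
    m <- jury_matrices(a)
    n <- 4
    X <- Y <- matrix(0, n - 1, n - 1)
    for (r in 1:(n - 1)) for (cc in 1:(n - 1)) {
      kx <- n - cc + r
      if (kx >= 0 && kx <= n) X[r, cc] <- a[kx + 1]
      ky <- r + cc - n
      if (ky >= 0 && ky <= n) Y[r, cc] <- a[ky + 1]
    }
    expect_equal(m$X, X)
    expect_equal(m$Y, Y)
  }
  expect_error(jury_matrices(c(1, 2)), "degree")
})

test_that("the Schur test agrees with an explicit root oracle", {
  expect_true(is_schur(poly_mult(poly_mult(c(0.01, 1), c(0.01, 1)),
                                 c(0.01, 1))))
  expect_false(is_schur(c(-1, 1)))        # root on the unit circle
  set.seed(22)
  for (i in 1:100) {
    a <- stats::rnorm(4)
    if (abs(a[4]) < 0.1) a[4] <- 0.5
    expect_identical(is_schur(a), all(Mod(polyroot(a)) < 1))
  }
})

test_that("the designed loop is robustly stable over the uncertainty interval", {
  p <- nominal_params()
  ctrl <- nominal_controller()
  fam <- charpoly_family(ctrl, p, c(0.16, 0.36))
  rep <- family_stability_check(fam)
  expect_true(rep$verdict)
  expect_true(all(rep$conditions))
  # cross-validated by brute-force root checks at every grid point
  expect_true(all(rep$traces$schur))
})

test_that("family conditions and exhaustive root checks agree", {
  p <- nominal_params()
  ctrl <- nominal_controller()
  # grid resolution 1e-3 over the kexc interval
  fam <- charpoly_family(ctrl, p, c(0.16, 0.36))
  rep <- family_stability_check(fam, grid_size = 201)
  expect_identical(rep$verdict, all(rep$traces$schur))
  # a family containing z - 1 fails condition (ii)
  fam_bad <- poly_family(function(q) {
    # member with an exact root at z = 1: (z - 1)(z^2 + 0.2 z + 0.1)
    if (q > 0.5) poly_mult(c(-1, 1), c(0.1, 0.2, 1)) else fam$fun(0.2)
  }, c(0, 1), q0 = 0.2)
  rep_bad <- family_stability_check(fam_bad, grid_size = 51)
  expect_false(rep_bad$conditions[["ii"]])
  expect_false(rep_bad$verdict)
  expect_error(poly_family(function(q) c(1, 1), c(1, 1)), "interval")
  expect_error(family_stability_check(fam, grid_size = 1), "at least 2")
})

test_that("the certified stability interval covers the printed uncertainty range", {
  p <- nominal_params()
  ctrl <- nominal_controller()
  sm <- stability_margin(ctrl, p)
  expect_gte(sm$upper, 0.36)
  expect_lte(sm$lower, 0.16)
  # every grid point in the certified interval is individually Schur
  inside <- sm$grid >= sm$lower & sm$grid <= sm$upper
  schur <- vapply(sm$grid[inside], function(q) {
    is_schur(closed_loop_charpoly(ctrl, thyroid_params(kexc = q)))
  }, logical(1))
  expect_true(all(schur))
})

test_that("stability reports serialize to JSON with their traces", {
  rep <- family_stability_check(
    charpoly_family(nominal_controller(), nominal_params()), grid_size = 21)
  f <- withr::local_tempfile(fileext = ".json")
  g <- withr::local_tempfile(fileext = ".csv")
  write_stability_report(rep, f, g)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_true(obj$verdict)
  expect_equal(obj$grid_size, 21)
  expect_equal(nrow(utils::read.csv(g)), 21)
})
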
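test_that("noncentral chi-square moment polynomials are exact", {
  expect_identical(ncx2_moment_poly(0, 4), 1)
  expect_equal(ncx2_moment_poly(1, 4), c(4, 1))                 # nu + delta
  # (nu + delta)^2 + 2(nu + 2 delta) expanded
  expect_equal(ncx2_moment_poly(2, 4), c(4^2 + 2 * 4, 2 * 4 + 4, 1))
  expect_equal(ncx2_moment_poly(2, 7), c(7^2 + 2 * 7, 2 * 7 + 4, 1))
  # Monte-Carlo cross-check of the second moment at nu = 4, delta = 3
  set.seed(21)
  x <- rchisq(1e5, 4, ncp = 3)
  expect_equal(eval_poly(ncx2_moment_poly(2, 4), 3), mean(x^2),
               tolerance = 3 * sd(x^2) / sqrt(1e5))
})

test_that("F0 moment polynomials scale correctly and enforce existence", {
  d <- mi_dims(4, 20)
  # first moment: (nu1 + n lambda) nu2 / (nu1 (nu2 - 2)); plugging into the
  # unbiased estimator gives E(lambda_bar) = lambda
  m1 <- f0_moment_poly(1, d)
  expect_equal(m1, c(4 * 20 / (4 * 18), 24 * 20 / (4 * 18)), tolerance = 1e-12)
  lam <- 0.7
  expect_equal(lambda_bar(eval_poly(m1, lam), d), lam, tolerance = 1e-12)
  # second moment vs Monte-Carlo at lambda = 1
  set.seed(22)
  F0 <- rf(2e5, 4, 20, ncp = 24)
  expect_equal(eval_poly(f0_moment_poly(2, d), 1), mean(F0^2),
               tolerance = 3 * sd(F0^2) / sqrt(2e5))
  # nonexistence boundary: nu2 <= 2i
  expect_error(f0_moment_poly(10, d), "nu2 > 2i")
  expect_error(f0_moment_poly(5, mi_dims(2, 10)), "nu2 > 2i")
})

test_that("endpoint selection follows the median/mode rule with a safe fallback", {
  d24 <- mi_dims(4, 20)
  F0 <- compute_F0(6, d24)
  ab <- select_endpoints(F0, d24)
  med <- mahabn:::invL(F0, 0.5, 4, 20, 24) / 24
  expect_gt(med, 2)                       # above the chi-square(4) mode
  expect_equal(unname(ab[1]), 0.99 * med, tolerance = 1e-8)
  expect_equal(unname(ab[2]), mahabn:::invL(F0, 0.001, 4, 20, 24) / 24,
               tolerance = 1e-8)
  # nu1 = 2: mode 0, so the median rule applies whenever L_0.5 > 0
  d2 <- mi_dims(2, 20)
  F02 <- compute_F0(1.5, d2)
  ab2 <- select_endpoints(F02, d2)
  expect_equal(unname(ab2[1]), 0.99 * mahabn:::invL(F02, 0.5, 2, 20, 22) / 22,
               tolerance = 1e-8)
  # degenerate input falls back to the fixed chi-square interval
  ab0 <- select_endpoints(0, d24)
  expect_true(attr(ab0, "fallback"))
  expect_identical(unname(ab0[1]), 0)
  expect_equal(unname(ab0[2]), qchisq(0.999, 4))
  # property sweep: a < b over random configurations
  set.seed(23)
  for (k in 1:200) {
    nu1 <- sample(c(2, 4, 8), 1)
    nu2 <- sample(c(10, 20, 80), 1)
    F0k <- rexp(1, 1 / 3)
    abk <- select_endpoints(F0k, mi_dims(nu1, nu2))
    expect_lt(abk[1], abk[2])
  }
})

test_that("Bernstein target reproduces endpoints and improves with degree", {
  a <- 0; b <- 18; nu1 <- 4
  # r = 1 is linear interpolation of the survival function
  t1 <- bernstein_target_coeffs(a, b, 1, nu1)
  lam <- c(2, 9, 15)
  expect_equal(eval_poly(t1, lam),
               1 - (pchisq(a, nu1) * (b - lam) + pchisq(b, nu1) * (lam - a)) / (b - a),
               tolerance = 1e-12)
  sup_err <- vapply(c(4, 7, 10), function(r) {
    tgt <- bernstein_target_coeffs(a, b, r, nu1)
    grid <- seq(a, b, length.out = 400)
    # endpoint reproduction is exact in exact arithmetic; Horner evaluation
    # at b cancels catastrophically for large r, hence absolute tolerance
    expect_lt(abs(eval_poly(tgt, a) - (1 - pchisq(a, nu1))), 1e-9)
    expect_lt(abs(eval_poly(tgt, b) - (1 - pchisq(b, nu1))), 1e-7)
    max(abs(eval_poly(tgt, grid) - (1 - pchisq(grid, nu1))))
  }, numeric(1))
  expect_true(all(diff(sup_err) < 0))  # 4 -> 7 -> 10 improves
  expect_lt(sup_err[2], 0.11)
})

test_that("quadrature target integrates the density accurately on a good interval", {
  nu1 <- 4; a <- 4; b <- 30; r <- 7
  tq <- quadrature_target_coeffs(a, b, r, nu1)
  expect_equal(eval_poly(tq, a), 1 - pchisq(a, nu1), tolerance = 1e-10)
  grid <- seq(a, b, length.out = 400)
  sup_q <- max(abs(eval_poly(tq, grid) - (1 - pchisq(grid, nu1))))
  tb <- bernstein_target_coeffs(a, b, r, nu1)
  sup_b <- max(abs(eval_poly(tb, grid) - (1 - pchisq(grid, nu1))))
  expect_lt(sup_q, sup_b)  # quadrature clearly better above the mode
  expect_lt(sup_q, 0.01)
  # total mass of the approximated density approaches G(b) - G(a) as r grows
  mass_err <- vapply(c(4, 7, 10), function(r) {
    tq <- quadrature_target_coeffs(a, b, r, nu1)
    abs((eval_poly(tq, a) - eval_poly(tq, b)) - (pchisq(b, nu1) - pchisq(a, nu1)))
  }, numeric(1))
  expect_true(all(diff(mass_err) < 0))
  expect_lt(mass_err[3], 5e-3)
})

test_that("matched coefficients solve the triangular system to high accuracy", {
  # r = 0 degenerate case
  expect_equal(solve_matched_coeffs(0.3, list(1)), 0.3)
  # round-trip residual over every supported configuration
  for (nu1 in c(2, 4, 8)) for (nu2 in c(10, 20, 80)) for (r in c(4, 7, 10)) {
    if (nu2 <= 2 * r) next
    d <- mi_dims(nu1, nu2)
    tgt <- bernstein_target_coeffs(0.5, qchisq(0.995, nu1), r, nu1)
    moms <- lapply(0:r, f0_moment_poly, dims = d)
    b <- solve_matched_coeffs(tgt, moms)
    recon <- Reduce(`+`, Map(function(bi, m) bi * c(m, numeric(r + 1 - length(m))),
                             b, moms))
    expect_lt(max(abs(recon - tgt) / pmax(abs(tgt), 1)), 1e-9)
  }
})

test_that("the matched polynomial is unbiased for its target (Monte-Carlo oracle)", {
  set.seed(24)
  d <- mi_dims(4, 20); r <- 7; lambda <- 2
  a <- 0.5; b <- qchisq(0.999, 4) + 2
  tgt <- quadrature_target_coeffs(a, b, r, 4)
  bcf <- solve_matched_coeffs(tgt, lapply(0:r, f0_moment_poly, dims = d))
  F0 <- rf(3e4, 4, 20, ncp = 24 * lambda)
  vals <- eval_poly(bcf, F0)
  expect_equal(mean(vals), eval_poly(tgt, lambda),
               tolerance = 3 * sd(vals) / sqrt(3e4))
})

test_that("polynomial estimators enforce the degree constraint and are deterministic", {
  expect_error(estimate_PP(1, mi_dims(4, 10), degree = 7), "strictly less")
  expect_error(estimate_PP(1, mi_dims(2, 20), degree = 10), "strictly less")
  v1 <- estimate_PP(1.3, d420, degree = 7, family = "quadrature")$value
  v2 <- estimate_PP(1.3, d420, degree = 7, family = "quadrature")$value
  expect_identical(v1, v2)
  # clipping is opt-in and flagged
  d24 <- mi_dims(4, 24)
  raw <- estimate_PP(0.15, d24, degree = 4, family = "quadrature")
  expect_false(raw$in_range)
  clipped <- estimate_PP(0.15, d24, degree = 4, family = "quadrature", clip = TRUE)
  expect_identical(clipped$value, 1)
  expect_true(clipped$in_range)
})

test_that("quadrature estimators leave [0, 1] where the profile sweep says they do", {
  d24 <- mi_dims(4, 24)
  lo_grid <- seq(0.05, 0.5, by = 0.05)
  hi_grid <- seq(12.5, 29.5, by = 1.7)
  for (r in c(4, 7)) {
    lo <- mahabn:::pP_value(lo_grid, d24, r, "quadrature")
    hi <- mahabn:::pP_value(hi_grid, d24, r, "quadrature")
    expect_true(any(lo > 1))
    expect_true(any(hi < 0))
  }
})
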
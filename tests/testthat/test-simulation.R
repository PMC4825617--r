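test_that("true_lambda_from_P inverts the chi-square survival function", {
  expect_equal(true_lambda_from_P(0.5, 2), 2 * log(2), tolerance = 1e-10)
  expect_equal(true_lambda_from_P(0.01, 2), -2 * log(0.01), tolerance = 1e-10)
  expect_equal(true_lambda_from_P(0.9825, 4), 0.4, tolerance = 1e-3)
  expect_error(true_lambda_from_P(0, 2), "strictly inside")
  expect_error(true_lambda_from_P(1, 2), "strictly inside")
})

test_that("case profiles carry exactly the requested index", {
  expect_identical(make_case_profile(0, 5), rep(0, 5))
  expect_identical(make_case_profile(4, 4), rep(1, 4))
  for (lam in c(0.3, 2, 9.21)) for (nu1 in c(2, 4, 8)) {
    x <- make_case_profile(lam, nu1)
    expect_equal(sum(x^2), lam, tolerance = 1e-12)  # index under (0, I)
  }
})

test_that("the two sampling routes agree in distribution", {
  set.seed(31)
  d <- mi_dims(4, 20)
  a <- simulate_lambda0(1, d, 3000, mode = "ncf_direct")
  b <- simulate_lambda0(1, d, 3000, mode = "mvn_full")
  expect_gt(suppressWarnings(ks.test(a, b))$p.value, 0.001)
  # direct draws reproduce the first moment of F0
  F0 <- compute_F0(simulate_lambda0(1, d, 1e5, mode = "ncf_direct"), d)
  expect_equal(mean(F0), eval_poly(f0_moment_poly(1, d), 1),
               tolerance = 3 * sd(F0) / sqrt(1e5))
  # central case: the empirical F0 median sits at the central-F median
  F0c <- compute_F0(simulate_lambda0(0, d, 2e4), d)
  expect_equal(median(F0c), qf(0.5, 4, 20), tolerance = 0.05)
})

test_that("run_study is reproducible and its metrics are coherent", {
  cfg <- sim_config(2, 10, true_P = c(0.05, 0.4), N = 500,
                    estimators = c("PF", "Pchi2", "PM"), seed = 99)
  s1 <- run_study(cfg)
  s2 <- run_study(cfg)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_true(all(s1$rmse_pp >= abs(s1$bias_pp) - 1e-9))
  expect_true(all(is.finite(as.matrix(s1[, 5:9]))))
  # changing the seed perturbs the draws
  s3 <- run_study(sim_config(2, 10, true_P = c(0.05, 0.4), N = 500,
                             estimators = c("PF", "Pchi2", "PM"), seed = 100))
  expect_false(identical(s1$bias_pp, s3$bias_pp))
  # a single replicate collapses the metrics onto one error
  s4 <- run_study(sim_config(2, 10, true_P = 0.1, N = 1, estimators = "PF",
                             seed = 1))
  expect_equal(s4$rmse_pp, abs(s4$bias_pp))
  expect_equal(s4$me_pp, s4$bias_pp)
  expect_equal(s4$aae_pp, abs(s4$bias_pp))
  # the mvn route runs end to end
  s5 <- run_study(sim_config(2, 8, true_P = 0.2, N = 50, estimators = "Pchi2",
                             sampling_mode = "mvn_full", seed = 5))
  expect_true(is.finite(s5$bias_pp))
})

test_that("invalid study configurations fail before any computation", {
  expect_error(sim_config(2, 10, estimators = "PX"), "unknown estimator")
  expect_error(sim_config(2, 10, estimators = "PQ10"), "unavailable")
  expect_error(sim_config(2, 10, true_P = 1.2), "strictly inside")
  expect_error(run_study(list()), "sim_config")
})

test_that("estimator sweeps flag exactly the unbounded families", {
  d24 <- mi_dims(4, 24)
  grid <- c(seq(0.05, 0.5, by = 0.05), seq(1, 30, by = 1))
  prof <- estimator_profile(d24, grid,
                            estimators = c("PF", "Pchi2", "PD", "PMD", "PM",
                                           "PR", "PT", "PQ4", "PQ7"))
  bounded <- prof$estimator %in% c("PF", "Pchi2", "PD", "PMD", "PM", "PR", "PT")
  expect_true(all(prof$n_above_1[bounded] == 0 & prof$n_below_0[bounded] == 0))
  quad <- prof$estimator %in% c("PQ4", "PQ7")
  expect_true(all(prof$n_above_1[quad] > 0))
  expect_true(all(prof$n_below_0[quad] > 0))
  # empty grid gives an empty table
  expect_identical(nrow(estimator_profile(d24, numeric(0))), 0L)
})
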
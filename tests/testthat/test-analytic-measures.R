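test_that("closed-form CV matches its special values and the moment oracle", {
  expect_equal(analytic_cv(gamma_spec(4, 1)), 0.5)
  expect_equal(analytic_cv(beta_spec(1, 1)), sqrt(1 / 12) / 0.5, tolerance = 1e-4)
  expect_equal(analytic_cv(beta_spec(1, 3)), sqrt(0.0375) / 0.25, tolerance = 1e-4)
  for (i in seq_len(nrow(beta_grid))) {
    spec <- beta_spec(beta_grid$p[i], beta_grid$q[i])
    mu <- oracle_moment(spec, 1)
    s2 <- oracle_moment(spec, 2) - mu^2
    expect_equal(analytic_cv(spec), sqrt(s2) / mu, tolerance = 1e-6)
  }
})

test_that("gamma skewness equals exactly twice the CV", {
  for (k in c(0.3, 0.5, 1, 2, 5, 40)) {
    spec <- gamma_spec(k, 1.3)
    expect_identical(analytic_skewness(spec), 2 * analytic_cv(spec))
  }
  expect_equal(analytic_skewness(gamma_spec(4, 1)), 1)
  expect_equal(analytic_skewness(gamma_spec(1, 1)), 2)
})

test_that("closed-form Gini matches special values and the CDF-integral oracle", {
  expect_equal(analytic_gini(gamma_spec(1, 1)), 0.5, tolerance = 1e-12)
  expect_equal(analytic_gini(gamma_spec(0.5, 1)), 2 / pi, tolerance = 1e-12)
  expect_equal(analytic_gini(beta_spec(1, 1)), 1 / 3, tolerance = 1e-12)
  for (i in seq_len(nrow(beta_grid))) {
    spec <- beta_spec(beta_grid$p[i], beta_grid$q[i])
    expect_equal(analytic_gini(spec), oracle_gini(spec), tolerance = 1e-7)
  }
  for (i in seq_len(nrow(gamma_grid))) {
    spec <- gamma_spec(gamma_grid$k[i], gamma_grid$delta[i])
    expect_equal(analytic_gini(spec), oracle_gini(spec), tolerance = 1e-7)
  }
  # log-gamma-space evaluation survives very large shapes
  expect_true(is.finite(analytic_gini(beta_spec(5e5, 5e5))))
  expect_true(is.finite(analytic_gini(gamma_spec(1e6, 1))))
})

test_that("closed-form entropy matches special values and the integral oracle", {
  expect_equal(analytic_entropy(gamma_spec(1, 1)), 1)
  expect_equal(analytic_entropy(beta_spec(1, 1)), 0)
  expect_equal(analytic_entropy(beta_spec(1, 1, bounds(0, 100))), log(100))
  for (i in seq_len(nrow(beta_grid))) {
    spec <- beta_spec(beta_grid$p[i], beta_grid$q[i], bounds(0, 7))
    expect_equal(analytic_entropy(spec), oracle_entropy(spec), tolerance = 1e-6)
  }
  for (i in seq_len(nrow(gamma_grid))) {
    spec <- gamma_spec(gamma_grid$k[i], gamma_grid$delta[i])
    expect_equal(analytic_entropy(spec), oracle_entropy(spec), tolerance = 1e-6)
  }
})

test_that("Newton quantile range agrees with quantile-function oracles to 1e-9", {
  expect_equal(quantile_range95(beta_spec(1, 1)), 0.95)
  expect_equal(quantile_range95(gamma_spec(1, 1)), -log(0.025) + log(0.975),
               tolerance = 1e-12)
  expect_equal(quantile_range95(beta_spec(2, 2)), oracle_qrange95(beta_spec(2, 2)),
               tolerance = 1e-9)
  for (i in seq_len(nrow(beta_grid))) {
    spec <- beta_spec(beta_grid$p[i], beta_grid$q[i], bounds(0, 50))
    expect_equal(quantile_range95(spec), oracle_qrange95(spec), tolerance = 1e-9)
  }
  for (i in seq_len(nrow(gamma_grid))) {
    spec <- gamma_spec(gamma_grid$k[i], gamma_grid$delta[i])
    expect_equal(quantile_range95(spec), oracle_qrange95(spec), tolerance = 1e-9)
  }
})

test_that("bias curves reproduce the analytic mean-dependence shapes", {
  cv_var <- bias_curve(bounds(lower = 0), delta = 1, means = c(1, 2, 4),
                       measures = "variance")
  expect_equal(cv_var$value, c(1, 2, 4))
  cv_sd <- bias_curve(bounds(lower = 0), delta = 1, means = c(1, 2, 4),
                      measures = "sd")
  expect_equal(cv_sd$value, sqrt(c(1, 2, 4)))

  means <- seq(5, 395, length.out = 40)
  curves <- bias_curve(bounds(lower = 0), delta = 2, means = means)
  wide <- tidyr::pivot_wider(curves, names_from = measure, values_from = value)
  # delta curve is exactly flat
  expect_equal(diff(range(wide$delta)), 0)
  # variance strictly increasing and linear in the mean
  expect_true(all(diff(wide$variance) > 0))
  expect_equal(max(abs(diff(wide$variance, differences = 2))), 0, tolerance = 1e-8)
  # sd concave increasing, CV strictly decreasing
  expect_true(all(diff(wide$sd) > 0))
  expect_true(all(diff(wide$sd, differences = 2) < 0))
  expect_true(all(diff(wide$cv) < 0))
})

test_that("double-bounded variance peaks at the centre, symmetric about it", {
  means <- seq(0.1, 0.9, by = 0.05)
  curves <- bias_curve(bounds(0, 1), delta = 0.2, means = means,
                       measures = "variance")
  v <- curves$value
  expect_equal(which.max(v), which(means == 0.5))
  expect_equal(v, rev(v), tolerance = 1e-12)
})

test_that("bias curves flag undefined points as NA with a warning", {
  expect_warning(
    curves <- bias_curve(bounds(0, 1), delta = 0.2, means = c(0.5, 1),
                         measures = "variance"),
    "undefined"
  )
  expect_equal(curves$value[1], 0.2 * 0.25)
  expect_true(is.na(curves$value[2]))
})
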
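test_that("boundedness class follows which bounds are declared", {
  expect_identical(classify_bounds(bounds(0, 1)), "double")
  expect_identical(classify_bounds(bounds(lower = 0)), "lower")
  expect_identical(classify_bounds(bounds(upper = 100)), "upper")
  expect_identical(classify_bounds(bounds()), "unbounded")
  expect_error(bounds(1, 0), "invalid bounds")
  expect_error(bounds(1, 1), "invalid bounds")
})

test_that("standardization maps raw values onto the standard scale", {
  expect_equal(standardize(0, bounds(-1, 1)), 0.5)
  expect_equal(standardize(5, bounds(lower = 2)), 3)
  expect_equal(standardize(3, bounds(upper = 10)), 7)
  expect_equal(standardize(1.5, bounds()), 1.5)
  expect_error(standardize(-3, bounds(lower = 2)), "outside declared bounds")
})

test_that("mean-dispersion parameterization of the beta family inverts correctly", {
  u <- beta_from_mean_dispersion(0.5, 1 / 3)
  expect_equal(c(u$p, u$q), c(1, 1))
  s <- beta_from_mean_dispersion(0.25, 0.2)
  expect_equal(c(s$p, s$q), c(1, 3))
  s2 <- beta_from_mean_dispersion(0.5, 0.2)
  expect_equal(c(s2$p, s2$q), c(2, 2))

  expect_error(beta_from_mean_dispersion(0, 0.2), "at or below the lower bound")
  expect_error(beta_from_mean_dispersion(1, 0.2), "at or above the upper bound")
  expect_error(beta_from_mean_dispersion(0.5, 1.2), "inside \\(0, 1\\)")
})

test_that("beta moments match the closed forms", {
  m <- dist_moments(beta_spec(2, 2))
  expect_equal(m$mean, 0.5)
  expect_equal(m$variance, 0.05)
  expect_equal(m$delta, 0.2)
  m <- dist_moments(beta_spec(1, 1))
  expect_equal(m$variance, 1 / 12)
  expect_equal(m$delta, 1 / 3)
  m <- dist_moments(beta_spec(1, 3))
  expect_equal(c(m$mean, m$variance, m$delta), c(0.25, 0.0375, 0.2))
})

test_that("gamma moments and mean-dispersion conversion match the closed forms", {
  m <- dist_moments(gamma_spec(2, 3))
  expect_equal(c(m$mean, m$variance), c(6, 18))
  m <- dist_moments(gamma_spec(4, 0.5))
  expect_equal(c(m$mean, m$variance), c(2, 1))
  expect_equal(gamma_from_mean_dispersion(6, 3)$shape, 2)
  expect_equal(gamma_from_mean_dispersion(0.64, 0.64)$shape, 1)
  expect_error(gamma_from_mean_dispersion(0, 1), "at or below")
  expect_error(gamma_from_mean_dispersion(5, -1), "positive")
})

test_that("mean-dispersion round-trips hold for both families and general bounds", {
  for (mu in c(0.05, 0.3, 0.5, 0.9)) {
    for (d in c(0.05, 1 / 3, 0.8)) {
      m <- dist_moments(beta_from_mean_dispersion(mu, d))
      expect_equal(m$mean, mu, tolerance = 1e-10)
      expect_equal(m$delta, d, tolerance = 1e-10)
    }
  }
  # raw-scale bounds
  b <- bounds(-5, 45)
  m <- dist_moments(beta_from_mean_dispersion(10, 0.25, b))
  expect_equal(m$mean, 10, tolerance = 1e-10)
  expect_equal(m$delta, 0.25, tolerance = 1e-10)
  for (mu in c(0.5, 6, 300)) {
    for (d in c(0.2, 2, 40)) {
      m <- dist_moments(gamma_from_mean_dispersion(mu, d))
      expect_equal(m$mean, mu, tolerance = 1e-10)
      expect_equal(m$delta, d, tolerance = 1e-10)
    }
  }
  m <- dist_moments(gamma_from_mean_dispersion(90, 2, bounds(upper = 100)))
  expect_equal(m$mean, 90, tolerance = 1e-10)
})

test_that("general-bound densities integrate to one with the correct moments", {
  for (i in seq_len(nrow(beta_grid))) {
    spec <- beta_spec(beta_grid$p[i], beta_grid$q[i], bounds(2, 12))
    expect_equal(oracle_mass(spec), 1, tolerance = 1e-8)
    m <- dist_moments(spec)
    expect_equal(oracle_moment(spec, 1), m$mean, tolerance = 1e-6)
    expect_equal(oracle_moment(spec, 2) - oracle_moment(spec, 1)^2, m$variance,
                 tolerance = 1e-6)
  }
  for (k in c(0.5, 1, 2, 5)) {
    spec <- gamma_spec(k, 1.7, bounds(lower = 3))
    expect_equal(oracle_mass(spec), 1, tolerance = 1e-8)
    m <- dist_moments(spec)
    expect_equal(oracle_moment(spec, 1), m$mean, tolerance = 1e-6)
  }
})

test_that("pdf and cdf handle edges, flips, and out-of-support values", {
  expect_equal(dist_pdf(beta_spec(1, 1), 0.3), 1)
  expect_equal(dist_pdf(beta_spec(1, 1, bounds(0, 100)), 50), 0.01)
  expect_equal(dist_pdf(gamma_spec(1, 1), 0), 1)
  expect_equal(dist_pdf(gamma_spec(2, 1), -1), 0)  # outside support: density 0
  expect_identical(dist_pdf(beta_spec(0.5, 2), 0), Inf)  # edge singularity

  expect_equal(dist_cdf(beta_spec(1, 1), 0.3), 0.3)
  expect_equal(dist_cdf(gamma_spec(1, 1), log(2)), 0.5)
  flipped <- gamma_spec(1, 1, bounds(upper = 10))
  expect_equal(dist_cdf(flipped, 10), 1)
  v <- seq(0, 10, by = 0.5)
  expect_true(all(diff(dist_cdf(flipped, v)) >= 0))
})

test_that("distribution modes follow the shape parameters", {
  expect_equal(dist_mode(gamma_spec(2, 3)), 3)
  expect_equal(dist_mode(gamma_spec(0.5, 1)), 0)
  expect_equal(dist_mode(beta_spec(2, 2)), 0.5)
  expect_equal(dist_mode(gamma_spec(2, 3, bounds(upper = 10))), 7)
  # edge-peaked beta: nudged into the open support
  m <- dist_mode(beta_spec(0.5, 2))
  expect_gt(m, 0)
  expect_lt(m, 1e-6)
})

test_that("beta variance never exceeds its mu(1-mu) limit", {
  for (i in seq_len(nrow(beta_grid))) {
    m <- dist_moments(beta_spec(beta_grid$p[i], beta_grid$q[i]))
    expect_lt(m$variance, m$mean * (1 - m$mean))
  }
  # the limit is approached as the shapes shrink
  m_small <- dist_moments(beta_spec(1e-4, 1e-4))
  expect_gt(m_small$variance / (m_small$mean * (1 - m_small$mean)), 0.999)
})
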
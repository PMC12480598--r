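# Independent numerical oracles used across the suite. These deliberately
# avoid the closed forms and solvers under test: integration via
# stats::integrate on the density, quantiles via stats::qbeta/qgamma,
# Gini via the identity G = (1/mu) * integral F(1-F) and via the brute-force
# pair sum for samples.

oracle_moment <- function(spec, power = 1) {
  f <- function(x) x^power * deltadisp::dist_pdf(spec, x)
  b <- spec$bounds
  lo <- if (is.null(b$lower)) -Inf else b$lower
  hi <- if (is.null(b$upper)) Inf else b$upper
  stats::integrate(f, lo, hi, rel.tol = 1e-10)$value
}

oracle_mass <- function(spec) {
  f <- function(x) deltadisp::dist_pdf(spec, x)
  b <- spec$bounds
  lo <- if (is.null(b$lower)) -Inf else b$lower
  hi <- if (is.null(b$upper)) Inf else b$upper
  stats::integrate(f, lo, hi, rel.tol = 1e-10)$value
}

# Gini on the standardized (nonnegative) scale: G = (1/mu) int F(1-F) dx
oracle_gini <- function(spec) {
  if (inherits(spec, "beta_spec")) {
    p <- spec$p; q <- spec$q
    mu <- p / (p + q)
    f <- function(x) stats::pbeta(x, p, q) * (1 - stats::pbeta(x, p, q))
    stats::integrate(f, 0, 1, rel.tol = 1e-10)$value / mu
  } else {
    k <- spec$shape; sc <- spec$dispersion
    mu <- k * sc
    f <- function(x) stats::pgamma(x, k, scale = sc) * (1 - stats::pgamma(x, k, scale = sc))
    stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value / mu
  }
}

# -int f log f on the standard scale, plus log(width) for double bounds
oracle_entropy <- function(spec) {
  if (inherits(spec, "beta_spec")) {
    p <- spec$p; q <- spec$q
    f <- function(x) {
      d <- stats::dbeta(x, p, q)
      ifelse(d > 0, -d * log(d), 0)
    }
    stats::integrate(f, 0, 1, rel.tol = 1e-9)$value +
      log(spec$bounds$upper - spec$bounds$lower)
  } else {
    k <- spec$shape; sc <- spec$dispersion
    f <- function(x) {
      d <- stats::dgamma(x, k, scale = sc)
      ifelse(d > 0, -d * log(d), 0)
    }
    stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value
  }
}

oracle_qrange95 <- function(spec) {
  if (inherits(spec, "beta_spec")) {
    w <- spec$bounds$upper - spec$bounds$lower
    (stats::qbeta(0.975, spec$p, spec$q) - stats::qbeta(0.025, spec$p, spec$q)) * w
  } else {
    stats::qgamma(0.975, spec$shape, scale = spec$dispersion) -
      stats::qgamma(0.025, spec$shape, scale = spec$dispersion)
  }
}

brute_gini <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) s <- s + sum(abs(x[i] - x))
  s / (2 * n^2 * mean(x))
}

# parameter grids shared by oracle-equivalence tests
beta_grid <- expand.grid(p = c(0.5, 1, 2, 5), q = c(0.5, 1, 2, 5))
gamma_grid <- expand.grid(k = c(0.5, 1, 2, 5), delta = c(0.5, 1, 2))

# shared mean-balanced gamma tile simulation (the desk-scale study
# conditions: 200 tiles of 400 pixels, dispersion fixed at 2, means spread
# over [10, 400])
sim_gamma_tiles <- function(n_tiles = 200, tile_size = 400, delta = 2,
                            mean_range = c(10, 400), seed = 42) {
  tiles <- deltadisp::gen_tiles(n_tiles, tile_size = tile_size,
                                family = "gamma",
                                b = deltadisp::bounds(lower = 0),
                                mean_range = mean_range, delta = delta,
                                seed = seed)
  deltadisp::heterogeneity_profile(tiles$observations, value, tile,
                                   b = deltadisp::bounds(lower = 0))
}

slope_t <- function(y, x) {
  cf <- summary(stats::lm(y ~ x))$coefficients
  cf["x", "t value"]
}
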
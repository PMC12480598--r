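#' Closed-form coefficient of variation
#'
#' Computed on the standardized scale (the natural scale of the underlying
#' standard beta or gamma form). For the beta family
#' `CV = sqrt(sigma^2) * (p + q) / p`; for the gamma family the CV collapses
#' to `1 / sqrt(k)` — a function of the shape alone, which is why the CV
#' tracks skewness rather than dispersion.
#'
#' @param spec A [beta_spec()] or [gamma_spec()].
#' @return The coefficient of variation (dimensionless).
#' @examples
#' analytic_cv(gamma_spec(4, 1))  # 0.5
#' @export
analytic_cv <- function(spec) {
  UseMethod("analytic_cv")
}

#' @export
analytic_cv.beta_spec <- function(spec) {
  p <- spec$p; q <- spec$q
  s2 <- p * q / ((p + q)^2 * (1 + p + q))
  sqrt(s2) * (p + q) / p
}

#' @export
analytic_cv.gamma_spec <- function(spec) {
  1 / sqrt(spec$shape)
}

#' Closed-form skewness of a gamma specification
#'
#' `Skew = 2 / sqrt(k)`, i.e. exactly twice the coefficient of variation —
#' the identity that exposes the CV as a measure of shape/skewness for
#' gamma-distributed variables.
#'
#' @param spec A [gamma_spec()].
#' @return The skewness.
#' @examples
#' analytic_skewness(gamma_spec(4, 1))  # 1
#' @export
analytic_skewness <- function(spec) {
  stopifnot(inherits(spec, "gamma_spec"))
  2 / sqrt(spec$shape)
}

#' Closed-form Gini coefficient
#'
#' Half the relative mean absolute difference, evaluated on the standardized
#' variable (a location shift would change the relative difference, so the
#' Gini of a general-bound variable is defined on its standard form).
#' Beta: `2 B(2p, 2q) / (p B(p, q)^2)`; gamma:
#' `Gamma(k + 1/2) / (sqrt(pi) Gamma(k + 1))`. Both are evaluated in
#' log-gamma space so large shapes do not overflow.
#'
#' @param spec A [beta_spec()] or [gamma_spec()].
#' @return Gini coefficient in (0, 1).
#' @examples
#' analytic_gini(gamma_spec(1, 1))  # 0.5 (exponential)
#' analytic_gini(beta_spec(1, 1))   # 1/3 (uniform)
#' @export
analytic_gini <- function(spec) {
  UseMethod("analytic_gini")
}

#' @export
analytic_gini.beta_spec <- function(spec) {
  p <- spec$p; q <- spec$q
  exp(log(2) + lbeta(2 * p, 2 * q) - log(p) - 2 * lbeta(p, q))
}

#' @export
analytic_gini.gamma_spec <- function(spec) {
  k <- spec$shape
  exp(lgamma(k + 0.5) - 0.5 * log(pi) - lgamma(k + 1))
}

#' Closed-form differential entropy (nats)
#'
#' Beta (standard scale):
#' `ln B(p,q) - (p-1)(psi(p) - psi(p+q)) - (q-1)(psi(q) - psi(p+q))`;
#' gamma: `k + ln(delta) + ln Gamma(k) + (1-k) psi(k)` where `delta` is the
#' scale. Differential entropy changes under a change of scale: a general
#' double-bounded variable on \[L, U\] adds `ln(U - L)` (change of
#' variables), while pure location shifts and flips add nothing.
#'
#' @param spec A [beta_spec()] or [gamma_spec()].
#' @return Differential entropy in nats, on the raw scale of the variable.
#' @examples
#' analytic_entropy(gamma_spec(1, 1))            # 1 (Exp(1))
#' analytic_entropy(beta_spec(1, 1))             # 0 (uniform on [0,1])
#' analytic_entropy(beta_spec(1, 1, bounds(0, 100)))  # log(100)
#' @export
analytic_entropy <- function(spec) {
  UseMethod("analytic_entropy")
}

#' @export
analytic_entropy.beta_spec <- function(spec) {
  p <- spec$p; q <- spec$q
  h <- lbeta(p, q) -
    (p - 1) * (digamma(p) - digamma(p + q)) -
    (q - 1) * (digamma(q) - digamma(p + q))
  h + log(support_width(spec$bounds))
}

#' @export
analytic_entropy.gamma_spec <- function(spec) {
  k <- spec$shape
  k + log(spec$dispersion) + lgamma(k) + (1 - k) * digamma(k)
}

# Vectorized safeguarded Newton solver for distribution quantiles on the
# standard scale. F and f are vectorized cdf/pdf closures; x0 the seed
# (the mode); lo/hi bracket the open support. Tolerance on |F(x) - prob|.
newton_quantile <- function(F, f, prob, x0, lo, hi, tol = 1e-12, max_iter = 100L) {
  n <- max(length(prob), length(x0))
  prob <- rep_len(prob, n)
  x <- rep_len(x0, n)
  lo <- rep_len(lo, n)
  hi <- rep_len(hi, n)
  span <- ifelse(is.finite(hi - lo), hi - lo, 1)
  x <- pmin(pmax(x, lo + 1e-12 * span), hi - 1e-12 * span)
  done <- rep(FALSE, n)
  for (iter in seq_len(max_iter)) {
    err <- F(x) - prob
    done <- done | abs(err) <= tol
    if (all(done)) break
    dens <- f(x)
    step <- ifelse(done | !is.finite(dens) | dens <= 0, 0, err / dens)
    x_new <- x - step
    # clamp steps that leave the open support
    left <- !done & (x_new <= lo | !is.finite(x_new))
    right <- !done & x_new >= hi
    x_new[left] <- (x[left] + lo[left]) / 2
    x_new[right] <- (x[right] + hi[right]) / 2
    x <- x_new
  }
  if (!all(done)) {
    idx <- which(!done)
    x[idx] <- vapply(idx, function(i) {
      bisect_quantile(F, prob[i], lo[i], hi[i], tol = tol)
    }, numeric(1))
  }
  x
}

bisect_quantile <- function(F, prob, lo, hi, tol = 1e-12, max_iter = 200L) {
  if (!is.finite(hi)) {  # expand an upper bracket for unbounded support
    hi <- max(1, lo + 1)
    while (F(hi) < prob && is.finite(hi)) hi <- hi * 2
  }
  a <- lo; b <- hi
  for (i in seq_len(max_iter)) {
    m <- (a + b) / 2
    fm <- F(m) - prob
    if (abs(fm) <= tol || (b - a) / 2 < .Machine$double.eps * max(1, abs(m))) return(m)
    if (fm < 0) a <- m else b <- m
  }
  stop("quantile bisection failed to converge", call. = FALSE)
}

#' 0.95 quantile range
#'
#' The extent between the 0.025 and 0.975 quantiles,
#' `x[0.975] - x[0.025]`, solved from the distribution's CDF by Newton's
#' method (tolerance 1e-12) seeded at the mode, with a bisection fallback
#' bracketed by the support, and returned on the raw scale of the variable.
#'
#' @param spec A [beta_spec()] or [gamma_spec()].
#' @return The 0.95 quantile range in units of the variable.
#' @examples
#' quantile_range95(beta_spec(1, 1))   # 0.95
#' quantile_range95(gamma_spec(1, 1))  # ~3.664
#' @export
quantile_range95 <- function(spec) {
  qs <- dist_quantiles_std(spec, c(0.025, 0.975))
  width <- qs[2] - qs[1]
  if (inherits(spec, "beta_spec")) width * support_width(spec$bounds) else width
}

# quantiles on the standard scale, Newton-from-the-mode
dist_quantiles_std <- function(spec, probs) {
  sp <- std_params(spec)
  if (sp$family == "beta") {
    F <- function(x) stats::pbeta(x, sp$p, sp$q)
    f <- function(x) stats::dbeta(x, sp$p, sp$q)
    x0 <- (dist_mode(spec) - spec$bounds$lower) / support_width(spec$bounds)
    newton_quantile(F, f, probs, x0, lo = 0, hi = 1)
  } else {
    F <- function(x) stats::pgamma(x, shape = sp$k, scale = sp$scale)
    f <- function(x) stats::dgamma(x, shape = sp$k, scale = sp$scale)
    x0 <- if (sp$k >= 1) (sp$k - 1) * sp$scale else 0
    x0 <- max(x0, 1e-8 * sp$scale)  # keep the seed inside the open support
    newton_quantile(F, f, probs, x0, lo = 0, hi = Inf)
  }
}

# Vectorized gamma-family 0.95 quantile range for many (k, scale) pairs at
# once; used by the warp grid where 500 x 500 points are evaluated.
gamma_qrange95_vec <- function(shape, scale) {
  n <- max(length(shape), length(scale))
  shape <- rep_len(shape, n)
  scale <- rep_len(scale, n)
  F <- function(x) stats::pgamma(x, shape = shape, scale = scale)
  f <- function(x) stats::dgamma(x, shape = shape, scale = scale)
  x0 <- pmax((shape - 1) * scale, 1e-8 * scale)
  lo <- rep(0, n)
  hi <- rep(Inf, n)
  q_hi <- newton_quantile(function(x) F(x), f, rep(0.975, n), x0, lo, hi)
  q_lo <- newton_quantile(function(x) F(x), f, rep(0.025, n), x0, lo, hi)
  q_hi - q_lo
}

#' All closed-form heterogeneity measures of one specification
#'
#' @param spec A [beta_spec()] or [gamma_spec()].
#' @return A one-row tibble: `mean`, `sd`, `variance`, `cv`, `gini`,
#'   `entropy`, `range` (0.95 quantile range), `delta`. Mean, sd, variance
#'   and range are on the raw scale; cv and gini on the standardized scale;
#'   entropy in nats.
#' @export
analytic_profile <- function(spec) {
  m <- dist_moments(spec)
  tibble::tibble(
    mean = m$mean,
    sd = m$sd,
    variance = m$variance,
    cv = analytic_cv(spec),
    gini = analytic_gini(spec),
    entropy = analytic_entropy(spec),
    range = quantile_range95(spec),
    delta = m$delta
  )
}

measure_names <- function() c("sd", "variance", "cv", "gini", "entropy", "range", "delta")

#' Mean-bias curve of a heterogeneity measure at fixed dispersion
#'
#' Evaluates one or more closed-form heterogeneity measures along a grid of
#' means while holding the dispersion delta fixed — the theoretical
#' mean-dependence curve of each measure. The distribution family follows
#' the boundedness class: beta for double-bounded, (flipped) gamma for
#' single-bounded variables. The delta curve is flat by construction; every
#' other measure traces its mean-bias.
#'
#' @param b A [bounds()] object (single- or double-bounded).
#' @param delta Fixed dispersion (in (0, 1) for double-bounded variables;
#'   units of the variable otherwise).
#' @param means Numeric vector of means, strictly inside the bounds.
#' @param measures Character vector from `sd`, `variance`, `cv`, `gini`,
#'   `entropy`, `range`, `delta`.
#' @return A long tibble with columns `mean`, `measure`, `value`. Means at
#'   which a measure is undefined yield `NA` with a warning.
#' @examples
#' bias_curve(bounds(lower = 0), delta = 1, means = c(1, 2, 4),
#'            measures = c("variance", "delta"))
#' @export
bias_curve <- function(b, delta, means, measures = measure_names()) {
  b <- as_bounds(b)
  measures <- match.arg(measures, measure_names(), several.ok = TRUE)
  if (classify_bounds(b) == "unbounded") {
    stop("bias curves need at least one bound (unbounded dispersion is the ",
         "variance itself)", call. = FALSE)
  }
  rows <- purrr::map(means, function(mu) {
    prof <- tryCatch(
      analytic_profile(dist_from_mean_dispersion(mu, delta, b)),
      error = function(e) {
        warning("measure undefined at mean ", format(mu), ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    if (is.null(prof)) {
      tibble::tibble(mean = mu, measure = measures, value = NA_real_)
    } else {
      tibble::tibble(mean = mu, measure = measures,
                     value = unlist(prof[measures], use.names = FALSE))
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bias_curve_df", class(out))
  out
}
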
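#' Beta distribution specification with general bounds
#'
#' Describes a beta-distributed variable on an arbitrary double-bounded
#' interval \[L, U\]. On the standard \[0, 1\] scale the distribution has the
#' usual shape parameters `p` and `q`; a raw value `v` indexes the standard
#' density at `x = (v - L) / (U - L)`.
#'
#' The (mean, dispersion) parameterization is available through
#' [beta_from_mean_dispersion()]: the standardized mean is
#' `mu = p / (p + q)` and the dispersion `delta2 = 1 / (1 + p + q)`,
#' both on the open interval (0, 1).
#'
#' @param p,q Positive shape parameters.
#' @param bounds A [bounds()] object with both bounds present
#'   (default the unit interval).
#' @return An object of class `beta_spec`.
#' @examples
#' beta_spec(2, 2)
#' beta_spec(1, 3, bounds(0, 100))
#' @export
beta_spec <- function(p, q, bounds = deltadisp::bounds(0, 1)) {
  stopifnot(is.numeric(p), length(p) == 1L, is.numeric(q), length(q) == 1L)
  if (!(p > 0 && q > 0)) stop("beta shapes `p` and `q` must be positive", call. = FALSE)
  b <- as_bounds(bounds)
  if (classify_bounds(b) != "double") {
    stop("a beta specification needs both a lower and an upper bound", call. = FALSE)
  }
  structure(list(p = p, q = q, bounds = b), class = c("beta_spec", "dist_spec"))
}

#' Gamma distribution specification with a single general bound
#'
#' Describes a gamma-distributed variable with an arbitrary lower bound
#' (`x = v - L` indexes the standard density) or, for upper-bounded
#' variables, a conceptually flipped gamma where `x = U - v`. The dispersion
#' parameter is the usual gamma scale: `mu = shape * dispersion` and
#' `sigma^2 = mu * dispersion` on the standard scale, so `dispersion` is
#' exactly the mean-independent delta of the variable.
#'
#' @param shape Positive shape parameter `k`.
#' @param dispersion Positive scale parameter (units of the variable).
#' @param bounds A [bounds()] object with exactly one bound present
#'   (default lower bound zero).
#' @return An object of class `gamma_spec`.
#' @examples
#' gamma_spec(2, 3)                         # mean 6, variance 18
#' gamma_spec(2, 3, bounds(upper = 100))    # flipped: mean 94
#' @export
gamma_spec <- function(shape, dispersion, bounds = deltadisp::bounds(lower = 0)) {
  stopifnot(is.numeric(shape), length(shape) == 1L,
            is.numeric(dispersion), length(dispersion) == 1L)
  if (!(shape > 0)) stop("gamma `shape` must be positive", call. = FALSE)
  if (!(dispersion > 0)) stop("gamma `dispersion` must be positive", call. = FALSE)
  b <- as_bounds(bounds)
  cls <- classify_bounds(b)
  if (!cls %in% c("lower", "upper")) {
    stop("a gamma specification needs exactly one bound (lower, or upper for ",
         "the flipped form)", call. = FALSE)
  }
  structure(list(shape = shape, dispersion = dispersion, bounds = b,
                 orientation = cls),
            class = c("gamma_spec", "dist_spec"))
}

#' @export
print.beta_spec <- function(x, ...) {
  cat(sprintf("<beta_spec p=%g q=%g on [%g, %g]>\n",
              x$p, x$q, x$bounds$lower, x$bounds$upper))
  invisible(x)
}

#' @export
print.gamma_spec <- function(x, ...) {
  side <- if (x$orientation == "lower") sprintf("L=%g", x$bounds$lower)
          else sprintf("U=%g (flipped)", x$bounds$upper)
  cat(sprintf("<gamma_spec k=%g dispersion=%g %s>\n", x$shape, x$dispersion, side))
  invisible(x)
}

#' Beta specification from mean and dispersion
#'
#' Inverts the (mean, delta2) parameterization: on the standard scale
#' `p = mu * (1 / delta2 - 1)` and `q = (1 - mu) * (1 / delta2 - 1)`.
#' The mean is given on the raw scale of the variable and standardized
#' internally via its bounds.
#'
#' @param mean Mean on the raw scale, strictly inside the bounds.
#' @param delta Dispersion `delta2` on the open interval (0, 1)
#'   (dimensionless; invariant under rescaling of the variable).
#' @param bounds A [bounds()] object with both bounds present.
#' @return A [beta_spec()].
#' @examples
#' beta_from_mean_dispersion(0.5, 1/3)  # uniform: p = q = 1
#' beta_from_mean_dispersion(0.25, 0.2) # p = 1, q = 3
#' @export
beta_from_mean_dispersion <- function(mean, delta, bounds = deltadisp::bounds(0, 1)) {
  b <- as_bounds(bounds)
  if (classify_bounds(b) != "double") {
    stop("the beta family requires both bounds", call. = FALSE)
  }
  check_mean_interior(mean, b)
  if (!(delta > 0 && delta < 1)) {
    stop("beta dispersion `delta` must lie strictly inside (0, 1), got ",
         format(delta), call. = FALSE)
  }
  mu <- (mean - b$lower) / (b$upper - b$lower)
  nu <- 1 / delta - 1  # p + q
  beta_spec(p = mu * nu, q = (1 - mu) * nu, bounds = b)
}

#' Gamma specification from mean and dispersion
#'
#' On the standard scale `k = mu / delta`, where `mu` is the mean's distance
#' to the single bound and `delta` the dispersion (scale) parameter in the
#' variable's units.
#'
#' @param mean Mean on the raw scale, strictly inside the bound.
#' @param delta Positive dispersion in units of the variable.
#' @param bounds A [bounds()] object with exactly one bound.
#' @return A [gamma_spec()].
#' @examples
#' gamma_from_mean_dispersion(6, 3)  # k = 2
#' @export
gamma_from_mean_dispersion <- function(mean, delta, bounds = deltadisp::bounds(lower = 0)) {
  b <- as_bounds(bounds)
  if (!classify_bounds(b) %in% c("lower", "upper")) {
    stop("the gamma family requires exactly one bound", call. = FALSE)
  }
  check_mean_interior(mean, b)
  if (!(delta > 0)) stop("gamma dispersion `delta` must be positive", call. = FALSE)
  mu <- standardize(mean, b)
  gamma_spec(shape = mu / delta, dispersion = delta, bounds = b)
}

#' Distribution specification from mean and dispersion
#'
#' Dispatches on the boundedness class: double-bounded variables are
#' modelled as (general) beta, single-bounded as (possibly flipped) gamma.
#'
#' @inheritParams beta_from_mean_dispersion
#' @param bounds A [bounds()] object with at least one bound.
#' @return A [beta_spec()] or [gamma_spec()].
#' @export
dist_from_mean_dispersion <- function(mean, delta, bounds) {
  b <- as_bounds(bounds)
  switch(classify_bounds(b),
    double = beta_from_mean_dispersion(mean, delta, b),
    lower  = ,
    upper  = gamma_from_mean_dispersion(mean, delta, b),
    stop("an unbounded variable has no beta/gamma model; its dispersion is ",
         "the variance itself", call. = FALSE)
  )
}

#' Moments and dispersion of a distribution specification
#'
#' Returns the mean and variance on the raw scale of the variable together
#' with the dispersion delta. For the beta family
#' `mu = p / (p + q)`, `sigma^2 = p q / ((p + q)^2 (1 + p + q))` and
#' `delta2 = sigma^2 / (mu (1 - mu)) = 1 / (1 + p + q)` on the standard
#' scale; for the gamma family `mu = k * delta` and `sigma^2 = mu * delta`.
#'
#' @param spec A [beta_spec()] or [gamma_spec()].
#' @return A one-row tibble with columns `mean`, `variance`, `sd`, `delta`.
#' @examples
#' dist_moments(beta_spec(2, 2))   # mean 0.5, variance 0.05, delta 0.2
#' dist_moments(gamma_spec(2, 3))  # mean 6, variance 18, delta 3
#' @export
dist_moments <- function(spec) {
  UseMethod("dist_moments")
}

#' @export
dist_moments.beta_spec <- function(spec) {
  p <- spec$p; q <- spec$q
  mu <- p / (p + q)
  s2 <- p * q / ((p + q)^2 * (1 + p + q))
  w <- support_width(spec$bounds)
  tibble::tibble(
    mean = spec$bounds$lower + mu * w,
    variance = s2 * w^2,
    sd = sqrt(s2) * w,
    delta = 1 / (1 + p + q)
  )
}

#' @export
dist_moments.gamma_spec <- function(spec) {
  mu <- spec$shape * spec$dispersion
  s2 <- mu * spec$dispersion
  raw_mean <- if (spec$orientation == "lower") spec$bounds$lower + mu
              else spec$bounds$upper - mu
  tibble::tibble(mean = raw_mean, variance = s2, sd = sqrt(s2),
                 delta = spec$dispersion)
}

# standard-scale shapes for internal use
std_params <- function(spec) {
  if (inherits(spec, "beta_spec")) list(family = "beta", p = spec$p, q = spec$q)
  else list(family = "gamma", k = spec$shape, scale = spec$dispersion)
}

#' Probability density of a general beta or gamma specification
#'
#' The general-bound density is the standard density evaluated at the
#' standardized value, divided by the Jacobian of the standardization
#' (`U - L` for double-bounded variables; 1 for single-bounded shifts and
#' flips). Values outside the support have density zero; for beta shapes
#' below 1 the density at the corresponding support edge is `Inf`.
#'
#' @param spec A [beta_spec()] or [gamma_spec()].
#' @param v Numeric vector of raw-scale values.
#' @return Numeric vector of densities.
#' @examples
#' dist_pdf(beta_spec(1, 1, bounds(0, 100)), 50)  # 0.01
#' dist_pdf(gamma_spec(1, 1), 0)                  # 1
#' @export
dist_pdf <- function(spec, v) {
  UseMethod("dist_pdf")
}

#' @export
dist_pdf.beta_spec <- function(spec, v) {
  b <- spec$bounds
  w <- support_width(b)
  out <- numeric(length(v))
  inside <- v >= b$lower & v <= b$upper
  x <- (v[inside] - b$lower) / w
  out[inside] <- stats::dbeta(x, spec$p, spec$q) / w
  out
}

#' @export
dist_pdf.gamma_spec <- function(spec, v) {
  b <- spec$bounds
  out <- numeric(length(v))
  if (spec$orientation == "lower") {
    inside <- v >= b$lower
    x <- v[inside] - b$lower
  } else {
    inside <- v <= b$upper
    x <- b$upper - v[inside]
  }
  out[inside] <- stats::dgamma(x, shape = spec$shape, scale = spec$dispersion)
  out
}

#' Cumulative distribution function of a general beta or gamma specification
#'
#' The beta CDF is the regularized incomplete beta function of the
#' standardized value; the gamma CDF the regularized lower incomplete gamma
#' function. For upper-bounded (flipped gamma) variables
#' `P(V <= v) = 1 - F_gamma(U - v)`, so the CDF still runs from 0 at the
#' lower edge of the support to 1 at the bound.
#'
#' @inheritParams dist_pdf
#' @return Numeric vector of probabilities.
#' @export
dist_cdf <- function(spec, v) {
  UseMethod("dist_cdf")
}

#' @export
dist_cdf.beta_spec <- function(spec, v) {
  b <- spec$bounds
  x <- pmin(pmax((v - b$lower) / support_width(b), 0), 1)
  stats::pbeta(x, spec$p, spec$q)
}

#' @export
dist_cdf.gamma_spec <- function(spec, v) {
  b <- spec$bounds
  if (spec$orientation == "lower") {
    stats::pgamma(pmax(v - b$lower, 0), shape = spec$shape, scale = spec$dispersion)
  } else {
    1 - stats::pgamma(pmax(b$upper - v, 0), shape = spec$shape, scale = spec$dispersion)
  }
}

#' Mode of a distribution specification (raw scale)
#'
#' Gamma: `(k - 1) * dispersion` for `k >= 1`, otherwise 0 (standard scale),
#' mapped back through the bound. Beta: `(p - 1) / (p + q - 2)` when both
#' shapes exceed 1; when either shape is at or below 1 the density peaks at a
#' support edge, and the edge value is nudged into the open support by
#' `1e-9 * (U - L)` so the result can seed Newton iterations.
#'
#' @param spec A [beta_spec()] or [gamma_spec()].
#' @return The mode on the raw scale.
#' @examples
#' dist_mode(gamma_spec(2, 3))  # 3
#' dist_mode(beta_spec(2, 2))   # 0.5
#' @export
dist_mode <- function(spec) {
  UseMethod("dist_mode")
}

#' @export
dist_mode.gamma_spec <- function(spec) {
  m <- if (spec$shape >= 1) (spec$shape - 1) * spec$dispersion else 0
  if (spec$orientation == "lower") spec$bounds$lower + m else spec$bounds$upper - m
}

#' @export
dist_mode.beta_spec <- function(spec) {
  p <- spec$p; q <- spec$q
  b <- spec$bounds
  w <- support_width(b)
  eps <- 1e-9
  x <- if (p > 1 && q > 1) {
    (p - 1) / (p + q - 2)
  } else if (p <= 1 && q <= 1) {
    # uniform or U-shaped: no single interior mode; centre keeps Newton seeds sane
    if (isTRUE(all.equal(p, q))) 0.5 else if (p < q) eps else 1 - eps
  } else if (p <= 1) {
    eps
  } else {
    1 - eps
  }
  b$lower + x * w
}
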
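#' Theoretical species-richness response surface
#'
#' A richness model with a quadratic (hump-shaped) mean-diversity
#' relationship and a linear, monotonically positive heterogeneity-diversity
#' relationship:
#' `D = b0 + b_mu * mu + b_mu2 * mu^2 + b_delta * delta (+ b_delta2 * delta^2)`.
#' The defaults are the coefficients of the elevation/breeding-bird surface
#' used throughout the package's simulations:
#' `D = 66.395 + 3.034e-2 mu - 1.188e-5 mu^2 + 1.076e-1 delta`.
#'
#' @param intercept,mu,mu2,delta,delta2 Model coefficients on raw scales.
#' @return An object of class `richness_model`.
#' @examples
#' richness_model()
#' @export
richness_model <- function(intercept = 66.395, mu = 3.034e-2,
                           mu2 = -1.188e-5, delta = 1.076e-1, delta2 = 0) {
  structure(list(intercept = intercept, mu = mu, mu2 = mu2,
                 delta = delta, delta2 = delta2),
            class = "richness_model")
}

#' @export
print.richness_model <- function(x, ...) {
  cat(sprintf("<richness_model D = %g + %g mu + %g mu^2 + %g delta%s>\n",
              x$intercept, x$mu, x$mu2, x$delta,
              if (x$delta2 != 0) sprintf(" + %g delta^2", x$delta2) else ""))
  invisible(x)
}

#' Evaluate the richness surface
#'
#' @param mu,delta Numeric vectors (recycled) of mean and dispersion.
#' @param model A [richness_model()].
#' @return Deterministic richness values.
#' @examples
#' richness_truth(0, 0)        # the intercept, 66.395
#' richness_truth(1000, 100)   # 95.615
#' @export
richness_truth <- function(mu, delta, model = richness_model()) {
  model$intercept + model$mu * mu + model$mu2 * mu^2 +
    model$delta * delta + model$delta2 * delta^2
}

#' Warp grid: heterogeneity measures across a (mean, delta) lattice
#'
#' Builds a Cartesian grid of true mean and true dispersion values,
#' evaluates the richness surface at each point, and computes every
#' closed-form heterogeneity measure for the distribution implied by the
#' family at that point. Because each mean-biased measure is a different
#' function of (mu, delta), plotting richness against such a measure warps
#' the rectangular lattice — the mechanism by which spurious hump-shaped
#' heterogeneity-diversity relationships arise.
#'
#' The default lattice spans means 64 to 2422 and dispersions 0.64 to 144
#' (elevation-like, gamma family with lower bound 0).
#'
#' @param n Points per axis (`n^2` grid points). 500 reproduces the
#'   polynomial-fit experiments; 50 is a fast mode.
#' @param mu_range,delta_range Length-2 ranges of the two axes.
#' @param model A [richness_model()].
#' @param family `"gamma"` (single-bounded) or `"beta"` (double-bounded).
#' @param b A [bounds()] object consistent with `family`.
#' @return A tibble with columns `mu`, `delta`, `richness`, `sd`,
#'   `variance`, `cv`, `gini`, `entropy`, `range`.
#' @export
make_warp_grid <- function(n = 500, mu_range = c(64, 2422),
                           delta_range = c(0.64, 144),
                           model = richness_model(),
                           family = c("gamma", "beta"),
                           b = bounds(lower = 0)) {
  family <- match.arg(family)
  stopifnot(n >= 2)
  b <- as_bounds(b)
  mus <- seq(mu_range[1], mu_range[2], length.out = n)
  deltas <- seq(delta_range[1], delta_range[2], length.out = n)
  grid <- tidyr::expand_grid(mu = mus, delta = deltas)
  if (family == "gamma") {
    if (!classify_bounds(b) %in% c("lower", "upper")) {
      stop("gamma family needs a single bound", call. = FALSE)
    }
    mu_std <- standardize(grid$mu, b)
    k <- mu_std / grid$delta
    s2 <- mu_std * grid$delta
    out <- dplyr::mutate(grid,
      richness = richness_truth(.data$mu, .data$delta, model),
      sd = sqrt(s2),
      variance = s2,
      cv = 1 / sqrt(k),
      gini = exp(lgamma(k + 0.5) - 0.5 * log(pi) - lgamma(k + 1)),
      entropy = k + log(.data$delta) + lgamma(k) + (1 - k) * digamma(k),
      range = gamma_qrange95_vec(k, .data$delta)
    )
  } else {
    if (classify_bounds(b) != "double") stop("beta family needs both bounds", call. = FALSE)
    bad <- grid$delta <= 0 | grid$delta >= 1
    if (any(bad)) {
      warning(sum(bad), " grid point(s) with delta outside (0, 1) dropped",
              call. = FALSE)
      grid <- grid[!bad, , drop = FALSE]
    }
    prof <- purrr::map2_dfr(grid$mu, grid$delta, function(m, d) {
      analytic_profile(beta_from_mean_dispersion(m, d, b))
    })
    out <- dplyr::bind_cols(grid,
      richness = richness_truth(grid$mu, grid$delta, model),
      prof[, c("sd", "variance", "cv", "gini", "entropy", "range")])
  }
  tibble::as_tibble(out)
}

new_hdr_fit <- function(fit, tag, data_name = NULL, rescaled = FALSE) {
  structure(list(fit = fit, tag = tag, rescaled = rescaled),
            class = "hdr_fit")
}

#' @export
print.hdr_fit <- function(x, ...) {
  cat("<hdr_fit ", x$tag, if (x$rescaled) ", predictors rescaled to [0,1]" else "",
      ">\n", sep = "")
  print(summary(x$fit)$coefficients)
  cat(sprintf("adjusted R^2 = %.4f, n = %d\n",
              summary(x$fit)$adj.r.squared, stats::nobs(x$fit)))
  invisible(x)
}

#' Fit a quadratic heterogeneity-diversity relationship
#'
#' OLS of richness on a heterogeneity measure and its square. On data from
#' a surface that is linear in true dispersion, a genuinely mean-independent
#' measure returns a quadratic coefficient indistinguishable from zero;
#' mean-biased measures return spurious curvature.
#'
#' @param data Data frame (e.g. a warp grid).
#' @param measure Name of the heterogeneity column.
#' @param response Name of the response column (default `"richness"`).
#' @param rescale Min-max rescale the measure to \[0, 1\] before fitting, so
#'   linear and quadratic coefficients are comparable across measures.
#' @return An `hdr_fit` object; see [tidy.hdr_fit()], [glance.hdr_fit()].
#' @export
fit_quadratic_hdr <- function(data, measure, response = "richness",
                              rescale = FALSE) {
  stopifnot(is.data.frame(data), measure %in% names(data),
            response %in% names(data), nrow(data) >= 6L)
  x <- data[[measure]]
  if (rescale) {
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) == 0) stop("cannot rescale a constant measure", call. = FALSE)
    x <- (x - rng[1]) / diff(rng)
  }
  df <- data.frame(y = data[[response]], m = x, m2 = x^2)
  fit <- stats::lm(y ~ m + m2, data = df)
  if (stats::df.residual(fit) < 1 || any(is.na(stats::coef(fit)))) {
    stop("rank-deficient quadratic fit for measure '", measure, "'", call. = FALSE)
  }
  new_hdr_fit(fit, tag = paste0("quadratic:", measure), rescaled = rescale)
}

suite_formulas <- function() {
  list(
    "#1" = y ~ mu + rho + rho2,
    "#2" = y ~ mu + mu2 + rho + rho2,
    "#3" = y ~ mu + delta + delta2,
    "#4" = y ~ mu + mu2 + delta + delta2,
    "#5" = y ~ mu + mu2 + delta
  )
}

#' Fit the five-model richness regression suite
#'
#' The standard comparison set for disentangling mean- and
#' heterogeneity-diversity relationships in gridded survey data. Models #1
#' and #2 use the range `rho` as the heterogeneity measure (quadratic, to
#' admit a hump); #3-#5 use the mean-independent `delta`; #2, #4 and #5 add
#' the quadratic mean term that captures a hump-shaped mean-diversity
#' relationship:
#' \describe{
#'   \item{#1}{`D ~ mu + rho + rho^2`}
#'   \item{#2}{`D ~ mu + mu^2 + rho + rho^2`}
#'   \item{#3}{`D ~ mu + delta + delta^2`}
#'   \item{#4}{`D ~ mu + mu^2 + delta + delta^2`}
#'   \item{#5}{`D ~ mu + mu^2 + delta`}
#' }
#' Independent variables are min-max rescaled to \[0, 1\] (after any
#' filtering) before fitting so effect sizes are comparable; set
#' `rescale = FALSE` to fit on raw scales (e.g. for coefficient-recovery
#' checks against a known surface). Each fit also reports the one-sided F
#' test against the intercept-only model.
#'
#' @param cells Data frame with columns `D` (richness), `mu`, `delta`,
#'   `rho`, and at least 20 rows.
#' @param models Integer subset of 1:5.
#' @param rescale Min-max rescale predictors before fitting (default TRUE).
#' @return A named list of `hdr_fit` objects with class `hdr_suite`.
#' @export
fit_model_suite <- function(cells, models = 1:5, rescale = TRUE) {
  need <- c("D", "mu", "delta", "rho")
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols)) {
    stop("cells table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(nrow(cells) >= 20L, all(models %in% 1:5))
  sc <- function(x) {
    if (!rescale) return(x)
    rng <- range(x, na.rm = TRUE)
    (x - rng[1]) / diff(rng)
  }
  df <- data.frame(y = cells$D, mu = sc(cells$mu), delta = sc(cells$delta),
                   rho = sc(cells$rho))
  df$mu2 <- df$mu^2
  df$delta2 <- df$delta^2
  df$rho2 <- df$rho^2
  fml <- suite_formulas()
  fits <- purrr::map(models, function(i) {
    tag <- paste0("#", i)
    new_hdr_fit(stats::lm(fml[[tag]], data = df), tag = tag, rescaled = rescale)
  })
  names(fits) <- paste0("#", models)
  structure(fits, class = "hdr_suite")
}

#' @export
print.hdr_suite <- function(x, ...) {
  for (f in x) print(f)
  invisible(x)
}

#' Nested extra-sum-of-squares F test
#'
#' Compares two OLS fits where the reduced model's terms are a subset of the
#' full model's, on the same data:
#' `F = ((RSS_r - RSS_f) / (df_r - df_f)) / (RSS_f / df_f)`.
#'
#' @param full,reduced `hdr_fit` objects or `lm` fits.
#' @return A one-row tibble: `F`, `df1`, `df2`, `p`.
#' @export
nested_f_test <- function(full, reduced) {
  lm_of <- function(x) if (inherits(x, "hdr_fit")) x$fit else x
  ff <- lm_of(full); fr <- lm_of(reduced)
  tf <- attr(stats::terms(ff), "term.labels")
  tr <- attr(stats::terms(fr), "term.labels")
  if (!all(tr %in% tf)) {
    stop("models are not nested: reduced terms are not a subset of full terms",
         call. = FALSE)
  }
  if (stats::nobs(ff) != stats::nobs(fr)) {
    stop("models were fit on different numbers of observations", call. = FALSE)
  }
  rss_f <- sum(stats::residuals(ff)^2)
  rss_r <- sum(stats::residuals(fr)^2)
  df_f <- stats::df.residual(ff)
  df_r <- stats::df.residual(fr)
  df1 <- df_r - df_f
  if (df1 == 0) {
    return(tibble::tibble(F = 0, df1 = 0, df2 = df_f, p = 1))
  }
  F <- ((rss_r - rss_f) / df1) / (rss_f / df_f)
  tibble::tibble(F = F, df1 = df1, df2 = df_f,
                 p = stats::pf(F, df1, df_f, lower.tail = FALSE))
}

#' Filter out partially covered border cells
#'
#' Grid cells only partially covering the survey region receive less
#' sampling effort; keeping them biases richness models. Retains cells with
#' coverage at or above the threshold (default 1: fully interior cells).
#'
#' @param cells Data frame of cells.
#' @param coverage Name of the coverage-fraction column (values in \[0, 1\]).
#' @param threshold Minimum coverage retained.
#' @return The filtered tibble.
#' @export
border_cell_filter <- function(cells, coverage = "coverage", threshold = 1.0) {
  stopifnot(coverage %in% names(cells))
  cv <- cells[[coverage]]
  stopifnot(all(cv >= 0 & cv <= 1, na.rm = TRUE))
  tibble::as_tibble(cells[!is.na(cv) & cv >= threshold, , drop = FALSE])
}

#' Tidy an HDR fit
#'
#' @param x An `hdr_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `model`, `term`,
#'   `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.hdr_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(model = x$tag, term = rownames(cf),
                 estimate = cf[, "Estimate"], std.error = cf[, "Std. Error"],
                 statistic = cf[, "t value"], p.value = cf[, "Pr(>|t|)"])
}

#' Model-level summary of an HDR fit
#'
#' @param x An `hdr_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `adj.r.squared`, `sigma`,
#'   `f.statistic`, `f.p.value` (one-sided F against the intercept-only
#'   model), `df1`, `df2`, `n`.
#' @export
glance.hdr_fit <- function(x, ...) {
  s <- summary(x$fit)
  fs <- s$fstatistic
  tibble::tibble(model = x$tag,
                 adj.r.squared = s$adj.r.squared, sigma = s$sigma,
                 f.statistic = unname(fs[1]),
                 f.p.value = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
                 df1 = unname(fs[2]), df2 = unname(fs[3]),
                 n = stats::nobs(x$fit))
}

#' @export
tidy.hdr_suite <- function(x, ...) {
  purrr::map_dfr(unclass(x), tidy)
}

#' @export
glance.hdr_suite <- function(x, ...) {
  purrr::map_dfr(unclass(x), glance)
}
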
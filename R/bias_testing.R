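#' Mean-balanced stratified resample of a tile table
#'
#' Emulates two-phase stratified sampling: tiles (rows of a profile table)
#' are binned by their mean into uniformly spaced strata, then up to
#' `per_stratum` tiles are resampled from each stratum — with replacement
#' when a stratum holds fewer tiles than requested. The result gives every
#' mean value roughly equal weight, so mean-heterogeneity relationships can
#' be read without the raw mean distribution dominating. Optional filters
#' mirror common raster hygiene: a cap on the tile mean and a minimum
#' valid-data fraction per tile.
#'
#' @param tiles A tibble with (at least) a `mean` column, e.g. from
#'   [heterogeneity_profile()].
#' @param n_strata Number of uniformly spaced mean bins (>= 2).
#' @param per_stratum Tiles drawn per stratum.
#' @param mean_range Length-2 numeric range defining the strata extent;
#'   default the observed range of `mean` after filtering.
#' @param mean_cap Optional upper cap: tiles with `mean > mean_cap` are
#'   dropped before stratification.
#' @param valid_fraction_col Optional column name holding each tile's valid
#'   data fraction in \[0, 1\].
#' @param min_valid_fraction Threshold for that fraction (default 0.75).
#' @param seed Optional integer seed for reproducible resampling.
#' @return A tibble of resampled tile rows with an added `stratum` column.
#' @export
mean_balanced_sample <- function(tiles, n_strata, per_stratum,
                                 mean_range = NULL, mean_cap = NULL,
                                 valid_fraction_col = NULL,
                                 min_valid_fraction = 0.75,
                                 seed = NULL) {
  stopifnot(is.data.frame(tiles), "mean" %in% names(tiles), n_strata >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(mean_cap)) tiles <- dplyr::filter(tiles, .data$mean <= mean_cap)
  if (!is.null(valid_fraction_col)) {
    tiles <- tiles[tiles[[valid_fraction_col]] >= min_valid_fraction, , drop = FALSE]
  }
  if (nrow(tiles) == 0L) stop("no tiles left after filtering", call. = FALSE)
  if (is.null(mean_range)) mean_range <- range(tiles$mean)
  edges <- seq(mean_range[1], mean_range[2], length.out = n_strata + 1L)
  stratum <- cut(tiles$mean, breaks = edges, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(stratum)
  tiles <- tiles[keep, , drop = FALSE]
  stratum <- stratum[keep]
  picked <- purrr::map(seq_len(n_strata), function(s) {
    idx <- which(stratum == s)
    if (length(idx) == 0L) {
      warning("stratum ", s, " is empty and was skipped", call. = FALSE)
      return(integer(0))
    }
    sample(idx, per_stratum, replace = length(idx) < per_stratum)
  })
  out <- tiles[unlist(picked), , drop = FALSE]
  out$stratum <- rep(seq_len(n_strata), vapply(picked, length, integer(1)))
  tibble::as_tibble(out)
}

# model-form predictor of a measure from the tile mean, without the delta
# scale: sd ~ sqrt(g(m)), variance ~ g(m), cv ~ sqrt(g(m))/m, where g(m) is
# the mean's distance product to the bound(s)
mean_form_predictor <- function(means, measure, b) {
  b <- as_bounds(b)
  g <- switch(classify_bounds(b),
    lower  = means - b$lower,
    upper  = b$upper - means,
    double = (means - b$lower) * (b$upper - means),
    stop("predictions require a bounded variable", call. = FALSE)
  )
  g[g < 0] <- NA_real_
  switch(measure,
    sd = sqrt(g),
    variance = g,
    cv = sqrt(g) / means,
    stop("no mean-form prediction for measure '", measure, "'", call. = FALSE)
  )
}

#' Predict a heterogeneity measure from tile means via the delta model
#'
#' The analytic mean-bias model: with the across-tile average dispersion
#' held fixed, each tile's sd, variance or CV is predicted from its mean
#' alone. Lower-bounded: `s = sqrt(db * (m - L))`, `s^2 = db * (m - L)`,
#' `CV = sqrt(dm * (m - L)) / m`; double-bounded variables replace
#' `(m - L)` with `(m - L)(U - m)`. Here `db` is the across-tile mean of the
#' estimated delta and `dm` its median — the median resists the blow-up of
#' delta estimates at small means and is therefore used for the CV.
#'
#' @param tiles Tibble with `mean` and `delta` columns.
#' @param measure One of `"sd"`, `"variance"`, `"cv"`.
#' @param b A [bounds()] object (single- or double-bounded).
#' @param delta_average `"mean"` or `"median"`; defaults to mean for
#'   sd/variance and median for cv.
#' @return A tibble with columns `mean`, `predicted`, and the
#'   `delta_average` used (as an attribute `"delta_average"`).
#' @export
predict_measure_from_mean <- function(tiles, measure = c("sd", "variance", "cv"),
                                      b, delta_average = NULL) {
  measure <- match.arg(measure)
  stopifnot(all(c("mean", "delta") %in% names(tiles)))
  if (is.null(delta_average)) {
    delta_average <- if (measure == "cv") "median" else "mean"
  }
  delta_average <- match.arg(delta_average, c("mean", "median"))
  dbar <- if (delta_average == "mean") mean(tiles$delta, na.rm = TRUE)
          else stats::median(tiles$delta, na.rm = TRUE)
  pred <- dbar * mean_form_predictor(tiles$mean, "variance", b)
  pred <- switch(measure,
    variance = pred,
    sd = sqrt(pred),
    cv = sqrt(pred) / tiles$mean
  )
  out <- tibble::tibble(mean = tiles$mean, predicted = pred)
  attr(out, "delta_average") <- delta_average
  out
}

#' Null prediction: no relationship with the mean
#'
#' Every tile's measure is predicted by the across-tile average of the
#' observed measure — the reference model against which the analytic
#' mean-bias model is compared.
#'
#' @param tiles Tibble holding the observed measure.
#' @param measure Column name of the observed measure.
#' @return A tibble with columns `mean` (if present) and `predicted`
#'   (constant).
#' @export
null_predict <- function(tiles, measure) {
  stopifnot(measure %in% names(tiles))
  tibble::tibble(
    mean = if ("mean" %in% names(tiles)) tiles$mean else NA_real_,
    predicted = rep(mean(tiles[[measure]], na.rm = TRUE), nrow(tiles))
  )
}

#' Paired t comparison of two squared-error vectors
#'
#' Two-sided paired-sample t-test on per-tile differences of squared
#' prediction errors (relying on the central limit theorem for normality).
#' A negative `t` means model A has the smaller errors. Exact ties across
#' all pairs give `t = 0, p = 1` when the mean difference is zero, and an
#' infinite-t sentinel (flagged `exact_tie`) when the difference is constant
#' but nonzero.
#'
#' @param err2_a,err2_b Equal-length numeric vectors of squared errors.
#' @return A one-row tibble: `t`, `df`, `p`, `mse_a`, `mse_b`, `exact_tie`.
#' @examples
#' compare_paired_t(c(1, 2, 3), c(2, 4, 6))
#' @export
compare_paired_t <- function(err2_a, err2_b) {
  stopifnot(length(err2_a) == length(err2_b), length(err2_a) >= 2L)
  d <- err2_a - err2_b
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    m <- mean(d)
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
    return(tibble::tibble(t = t, df = n - 1, p = p,
                          mse_a = mean(err2_a), mse_b = mean(err2_b),
                          exact_tie = TRUE))
  }
  t <- mean(d) / (sd_d / sqrt(n))
  tibble::tibble(t = t, df = n - 1,
                 p = 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE),
                 mse_a = mean(err2_a), mse_b = mean(err2_b),
                 exact_tie = FALSE)
}

#' Compare the analytic mean-bias model against the null model
#'
#' For each of sd, variance and CV: predict the measure from the tile means
#' via [predict_measure_from_mean()], predict it by the across-tile average
#' via [null_predict()], and compare the two squared-error vectors with a
#' paired t-test. A negative `t` with small `p` says the analytic
#' mean-dependence model explains the observed measure better than assuming
#' no mean relationship — the signature of a mean-biased measure.
#'
#' @param tiles Profile tibble with `mean`, `delta` and the measure columns.
#' @param b A [bounds()] object.
#' @param measures Measures to test (default sd, variance, cv).
#' @return A tibble, one row per measure: `measure`, `mse_analytic`,
#'   `mse_null`, `t`, `df`, `p`, `delta_average`.
#' @export
bias_model_comparison <- function(tiles, b, measures = c("sd", "variance", "cv")) {
  purrr::map_dfr(measures, function(ms) {
    obs <- tiles[[ms]]
    pa <- predict_measure_from_mean(tiles, ms, b)
    pn <- null_predict(tiles, ms)
    ok <- stats::complete.cases(obs, pa$predicted, pn$predicted)
    cmp <- compare_paired_t((obs - pa$predicted)[ok]^2, (obs - pn$predicted)[ok]^2)
    tibble::tibble(measure = ms,
                   mse_analytic = cmp$mse_a, mse_null = cmp$mse_b,
                   t = cmp$t, df = cmp$df, p = cmp$p,
                   delta_average = attr(pa, "delta_average"))
  })
}

#' Equivalence (TOST) test of delta's mean-independence
#'
#' Tests whether the estimated delta's relationship with the mean is
#' negligible relative to a mean-biased reference measure. Both responses
#' (delta and the reference measure) are min-max rescaled to \[0, 1\]; the
#' predictor is the reference measure's mean-form model (its analytic
#' mean-dependence shape, without the delta scale); both rescaled responses
#' are regressed on it by OLS. Two one-sided t-tests then assess whether the
#' delta coefficient lies within plus/minus half the magnitude of the
#' reference coefficient. Rejection at `alpha` declares the mean-dependence
#' of delta negligible.
#'
#' @param tiles Profile tibble with `mean`, `delta` and the reference
#'   measure column.
#' @param reference One of `"sd"`, `"variance"`, `"cv"` — the mean-biased
#'   measure whose model form defines the predictor and the negligibility
#'   bound.
#' @param b A [bounds()] object.
#' @param alpha Significance level of the two one-sided tests (default 0.05).
#' @param response Optional column to test in place of `delta` (used e.g. to
#'   confirm the test rejects equivalence for a mean-biased response).
#' @return A one-row tibble: `reference`, `delta_coef`, `delta_se`,
#'   `reference_coef`, `negligible_bound`, `t`, `df`, `p`, `pass`.
#' @export
delta_negligibility_test <- function(tiles, reference = c("sd", "variance", "cv"),
                                     b, alpha = 0.05, response = "delta") {
  reference <- match.arg(reference)
  stopifnot(nrow(tiles) >= 10L,
            all(c("mean", response, reference) %in% names(tiles)))
  rescale01 <- function(x) {
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) == 0) stop("degenerate (constant) column; cannot rescale", call. = FALSE)
    (x - rng[1]) / diff(rng)
  }
  pred <- mean_form_predictor(tiles$mean, reference, b)
  if (stats::sd(pred, na.rm = TRUE) == 0) {
    stop("degenerate predictor: the mean-form predictor is constant", call. = FALSE)
  }
  y_delta <- rescale01(tiles[[response]])
  y_ref <- rescale01(tiles[[reference]])
  fit_d <- stats::lm(y_delta ~ pred)
  fit_r <- stats::lm(y_ref ~ pred)
  sm <- summary(fit_d)$coefficients
  b_d <- sm["pred", "Estimate"]
  se_d <- sm["pred", "Std. Error"]
  b_r <- stats::coef(fit_r)[["pred"]]
  bound <- abs(b_r) / 2
  df <- stats::df.residual(fit_d)
  t_low <- (b_d + bound) / se_d   # H0: b_d <= -bound
  t_high <- (bound - b_d) / se_d  # H0: b_d >= +bound
  p <- max(stats::pt(t_low, df, lower.tail = FALSE),
           stats::pt(t_high, df, lower.tail = FALSE))
  tibble::tibble(reference = reference,
                 delta_coef = b_d, delta_se = se_d, reference_coef = b_r,
                 negligible_bound = bound,
                 t = min(t_low, t_high), df = df, p = p,
                 pass = p < alpha)
}
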
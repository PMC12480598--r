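#' Summary statistics of one sample under a fixed variance convention
#'
#' @param x Numeric vector of observations.
#' @param b Optional [bounds()] object; values outside the bounds raise an
#'   error naming the offending positions.
#' @param ddof Delta degrees of freedom for the variance denominator
#'   `n - ddof`; 1 (the unbiased sample variance) by default, 0 for the
#'   population convention.
#' @return A one-row tibble: `n`, `mean`, `variance`, `sd`, `minimum`,
#'   `maximum`.
#' @examples
#' summarize_sample(c(2, 4, 6))  # mean 4, variance 4
#' @export
summarize_sample <- function(x, b = NULL, ddof = 1) {
  stopifnot(is.numeric(x), length(x) >= 1L, ddof %in% c(0, 1))
  x <- x[!is.na(x)]
  if (!is.null(b)) check_within_bounds(x, as_bounds(b))
  n <- length(x)
  m <- mean(x)
  v <- if (n > ddof) sum((x - m)^2) / (n - ddof) else NA_real_
  tibble::tibble(n = n, mean = m, variance = v, sd = sqrt(v),
                 minimum = min(x), maximum = max(x))
}

# delta from already-computed moments; shared by delta_hat and profiles
delta_from_moments <- function(mean, variance, b) {
  b <- as_bounds(b)
  check_mean_interior(mean, b)
  if (variance == 0) return(0)
  denom <- 1
  if (!is.null(b$lower)) denom <- denom * (mean - b$lower)
  if (!is.null(b$upper)) denom <- denom * (b$upper - mean)
  variance / denom
}

#' Estimate the mean-independent dispersion delta from a sample
#'
#' `delta = sigma^2 / ((mu - L)^1(L) * (U - mu)^1(U))`, where the indicator
#' exponents switch each bound's factor on only when that bound exists:
#' double-bounded variables give `delta2 = s^2 / ((m - L)(U - m))`
#' (dimensionless after standardization), single-bounded variables give
#' `deltaL = s^2 / (m - L)` or `deltaU = s^2 / (U - m)` (units of the
#' variable), and unbounded variables fall back to the variance itself.
#'
#' A constant sample has `delta = 0`; a sample mean sitting exactly on a
#' bound leaves delta undefined and raises an error.
#'
#' @param x Numeric vector of observations.
#' @param b A [bounds()] object.
#' @param ddof Variance convention passed to [summarize_sample()].
#' @return The estimated dispersion (scalar).
#' @examples
#' delta_hat(c(2, 4, 6), bounds(lower = 0))    # 1
#' delta_hat(c(0, 0.5, 1), bounds(0, 1))       # 1
#' @export
delta_hat <- function(x, b, ddof = 1) {
  s <- summarize_sample(x, b, ddof = ddof)
  delta_from_moments(s$mean, s$variance, b)
}

#' Sample coefficient of variation
#'
#' @inheritParams delta_hat
#' @return `sd / mean`; errors when the mean is zero.
#' @examples
#' cv_hat(c(2, 4, 6))  # 0.5
#' @export
cv_hat <- function(x, ddof = 1) {
  s <- summarize_sample(x, ddof = ddof)
  if (s$mean == 0) stop("coefficient of variation undefined at mean zero", call. = FALSE)
  s$sd / s$mean
}

#' Sample Gini coefficient
#'
#' Half the relative mean absolute difference over all ordered pairs
#' (including self-pairs): `sum_ij |x_i - x_j| / (2 n^2 mean)`. Computed via
#' the O(n log n) sorted-cumulative identity; intended for nonnegative
#' (standardized-scale) values.
#'
#' @param x Numeric vector of nonnegative observations with positive mean.
#' @return Gini coefficient.
#' @examples
#' gini_hat(c(0, 1))     # 0.5
#' gini_hat(c(1, 2, 3))  # 0.2222
#' @export
gini_hat <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  x <- x[!is.na(x)]
  if (any(x < 0)) stop("gini_hat expects nonnegative (standardized) values", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("Gini coefficient undefined at mean zero", call. = FALSE)
  n <- length(x)
  xs <- sort(x)
  # sum_ij |x_i - x_j| = 2 * sum_i (2i - n - 1) x_(i)
  sum_abs <- 2 * sum((2 * seq_len(n) - n - 1) * xs)
  sum_abs / (2 * n^2 * m)
}

#' Sample range of a distribution
#'
#' Two conventions are exposed: `"quantile"` returns the 0.95 quantile range
#' (extent between the linearly interpolated 0.025 and 0.975 empirical
#' quantiles), and `"minmax"` returns `max - min` — the convention used in
#' older elevation-range analyses.
#'
#' @param x Numeric vector, `n >= 2` for the quantile mode.
#' @param mode `"quantile"` (default) or `"minmax"`.
#' @return The range estimate.
#' @examples
#' qrange_hat(0:100)               # 95
#' qrange_hat(c(3, 9), "minmax")   # 6
#' @export
qrange_hat <- function(x, mode = c("quantile", "minmax")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]
  if (mode == "minmax") return(max(x) - min(x))
  stopifnot(length(x) >= 2L)
  qs <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  qs[2] - qs[1]
}

#' k-nearest-neighbour differential entropy estimator
#'
#' The Kozachenko-Leonenko estimator in one dimension:
#' `H = psi(n) - psi(k) + mean(log(2 r_k))`, where `r_k` is each point's
#' distance to its k-th nearest neighbour. Exact zero distances (heavy ties)
#' are floored at machine-epsilon scale before the logarithm. Consistent for
#' large `n`; band-free, unlike histogram entropies.
#'
#' @param x Numeric vector, `n > k`.
#' @param k Neighbour order (default 3).
#' @return Differential entropy estimate in nats.
#' @export
knn_entropy_hat <- function(x, k = 3L) {
  x <- x[!is.na(x)]
  n <- length(x)
  stopifnot(k >= 1L, n > k)
  xs <- sort(x)
  # in 1-D the k nearest neighbours of a sorted point lie within k positions
  cand <- matrix(Inf, n, 2L * k)
  for (j in seq_len(k)) {
    d <- xs[(1 + j):n] - xs[1:(n - j)]
    cand[(1 + j):n, j] <- d          # j-th neighbour to the left
    cand[1:(n - j), k + j] <- d      # j-th neighbour to the right
  }
  r_k <- apply(cand, 1L, function(r) sort(r, partial = k)[k])
  floor_d <- .Machine$double.eps * max(1, xs[n] - xs[1])
  r_k <- pmax(r_k, floor_d)
  digamma(n) - digamma(k) + mean(log(2 * r_k))
}

#' Banded Shannon entropy
#'
#' Shannon entropy of the occupancy proportions of predefined bands (e.g.
#' foliage height bands): `-sum p_i log p_i`, empty bands contributing
#' nothing. Sensitive to the choice of band edges, which is why the
#' band-free k-NN differential entropy is usually preferable.
#'
#' @param x Numeric vector.
#' @param edges Increasing numeric vector of band edges covering the data.
#' @return Entropy in nats.
#' @examples
#' band_shannon_hat(c(1, 1, 3, 3), edges = c(0, 2, 4))  # log(2)
#' @export
band_shannon_hat <- function(x, edges) {
  x <- x[!is.na(x)]
  stopifnot(length(edges) >= 2L, !is.unsorted(edges))
  bands <- cut(x, breaks = edges, include.lowest = TRUE)
  if (anyNA(bands)) {
    stop("values fall outside the band coverage [", edges[1], ", ",
         edges[length(edges)], "]", call. = FALSE)
  }
  p <- as.vector(table(bands)) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-group heterogeneity profiles of a tabular sample
#'
#' The workhorse estimator table: computes every heterogeneity measure —
#' sample mean, variance, sd, CV, Gini, k-NN differential entropy, range and
#' the mean-independent delta — for each group ("tile") of observations.
#' Gini is computed on the standardized values. Any measure that fails for a
#' group (e.g. CV at mean zero) is recorded as `NA` with a warning rather
#' than aborting the table.
#'
#' @param data A data frame of observations, one row per value.
#' @param value Column holding the observed values (tidy-eval).
#' @param group Optional grouping column (tidy-eval); omitted, the whole
#'   table is one sample.
#' @param b A [bounds()] object shared by all groups.
#' @param ddof Variance convention (see [summarize_sample()]).
#' @param range_mode `"quantile"` or `"minmax"` (see [qrange_hat()]).
#' @param entropy_k Neighbour order for [knn_entropy_hat()].
#' @return A tibble with one row per group: the grouping column (if any),
#'   `n`, `mean`, `variance`, `sd`, `cv`, `gini`, `entropy`, `range`,
#'   `delta`.
#' @examples
#' d <- data.frame(tile = rep(1:2, each = 3), v = c(2, 4, 6, 1, 2, 3))
#' heterogeneity_profile(d, v, tile, b = bounds(lower = 0))
#' @export
heterogeneity_profile <- function(data, value, group = NULL, b,
                                  ddof = 1, range_mode = c("quantile", "minmax"),
                                  entropy_k = 3L) {
  range_mode <- match.arg(range_mode)
  b <- as_bounds(b)
  vals <- dplyr::pull(data, {{ value }})
  check_within_bounds(vals, b)
  grp_quo <- rlang::enquo(group)
  if (rlang::quo_is_null(grp_quo)) {
    keys <- tibble::tibble(.rows = 1L)
    idx <- list(seq_along(vals))
  } else {
    gname <- names(dplyr::select(data, {{ group }}))[1]
    g <- data[[gname]]
    keys <- tibble::tibble(!!gname := unique(g))
    idx <- split(seq_along(vals), factor(g, levels = unique(g)))
  }
  safe <- function(expr) {
    tryCatch(expr, error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      NA_real_
    })
  }
  prof <- purrr::map(idx, function(i) {
    x <- vals[i]
    s <- summarize_sample(x, ddof = ddof)
    std <- standardize(x, b)
    tibble::tibble(
      n = s$n, mean = s$mean, variance = s$variance, sd = s$sd,
      cv = safe(cv_hat(x, ddof = ddof)),
      gini = safe(gini_hat(std)),
      entropy = safe(knn_entropy_hat(x, k = entropy_k)),
      range = safe(qrange_hat(x, mode = range_mode)),
      delta = safe(delta_from_moments(s$mean, s$variance, b))
    )
  })
  tibble::as_tibble(dplyr::bind_cols(keys, dplyr::bind_rows(prof)))
}
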
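#' Declare the bounds of a continuous variable
#'
#' A bounds specification records the conceptual or experimental lower and/or
#' upper limit of a continuous variable (e.g. `bounds(0, 100)` for a cover
#' percentage, `bounds(lower = 0)` for elevation above sea level). Which
#' bounds are present determines the boundedness class and thereby which
#' variant of the dispersion measure delta applies.
#'
#' Bounds should come from subject-matter knowledge, not from the observed
#' minimum/maximum of a small sample.
#'
#' @param lower Lower bound, or `NULL` if the variable has none.
#' @param upper Upper bound, or `NULL` if the variable has none.
#' @return An object of class `delta_bounds`.
#' @examples
#' bounds(0, 1)        # double-bounded (proportion)
#' bounds(lower = 0)   # lower-bounded (elevation, mass, ...)
#' bounds()            # unbounded
#' @export
bounds <- function(lower = NULL, upper = NULL) {
  if (!is.null(lower)) {
    stopifnot(is.numeric(lower), length(lower) == 1L)
    if (!is.finite(lower)) lower <- NULL
  }
  if (!is.null(upper)) {
    stopifnot(is.numeric(upper), length(upper) == 1L)
    if (!is.finite(upper)) upper <- NULL
  }
  if (!is.null(lower) && !is.null(upper) && lower >= upper) {
    stop("invalid bounds: `lower` (", lower, ") must be strictly below `upper` (",
         upper, ")", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper), class = "delta_bounds")
}

as_bounds <- function(x) {
  if (inherits(x, "delta_bounds")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(bounds(x[1], x[2]))
  stop("cannot interpret `", deparse(substitute(x)), "` as a bounds specification",
       call. = FALSE)
}

#' Boundedness class of a bounds specification
#'
#' @param b A [bounds()] object.
#' @return One of `"unbounded"`, `"lower"`, `"upper"`, `"double"`.
#' @examples
#' classify_bounds(bounds(0, 1))
#' classify_bounds(bounds(lower = 0))
#' @export
classify_bounds <- function(b) {
  b <- as_bounds(b)
  has_l <- !is.null(b$lower)
  has_u <- !is.null(b$upper)
  if (has_l && has_u) "double" else if (has_l) "lower" else if (has_u) "upper" else "unbounded"
}

#' @export
print.delta_bounds <- function(x, ...) {
  cls <- classify_bounds(x)
  l <- if (is.null(x$lower)) "-Inf" else format(x$lower)
  u <- if (is.null(x$upper)) "Inf" else format(x$upper)
  cat("<bounds: ", cls, " [", l, ", ", u, "]>\n", sep = "")
  invisible(x)
}

support_width <- function(b) {
  if (classify_bounds(b) != "double") Inf else b$upper - b$lower
}

#' Map a value onto the standard scale implied by its bounds
#'
#' Double-bounded values are rescaled to \[0, 1\] as `(v - L) / (U - L)`;
#' lower-bounded values are shifted so the bound sits at zero (`v - L`);
#' upper-bounded values are flipped about the bound (`U - v`), so the standard
#' gamma form applies; unbounded values pass through unchanged.
#'
#' @param v Numeric vector of values on the raw scale.
#' @param b A [bounds()] object.
#' @return Numeric vector on the standard scale.
#' @examples
#' standardize(0, bounds(-1, 1))    # 0.5
#' standardize(5, bounds(lower = 2)) # 3
#' standardize(3, bounds(upper = 10)) # 7
#' @export
standardize <- function(v, b) {
  b <- as_bounds(b)
  check_within_bounds(v, b)
  switch(classify_bounds(b),
    double = (v - b$lower) / (b$upper - b$lower),
    lower  = v - b$lower,
    upper  = b$upper - v,
    unbounded = v
  )
}

check_within_bounds <- function(v, b, what = "value") {
  bad <- logical(length(v))
  if (!is.null(b$lower)) bad <- bad | (v < b$lower)
  if (!is.null(b$upper)) bad <- bad | (v > b$upper)
  bad[is.na(v)] <- FALSE
  if (any(bad)) {
    idx <- which(bad)
    show <- utils::head(idx, 5L)
    stop(sprintf("%s outside declared bounds at %d position(s): %s%s",
                 what, length(idx), paste(show, collapse = ", "),
                 if (length(idx) > 5L) ", ..." else ""),
         call. = FALSE)
  }
  invisible(TRUE)
}

# means within 1e-12 of a bound make the delta denominator vanish; reject
check_mean_interior <- function(mean, b, tol = 1e-12) {
  width <- support_width(b)
  scale <- if (is.finite(width)) width else max(1, abs(mean))
  if (!is.null(b$lower) && mean - b$lower <= tol * scale) {
    stop("mean (", format(mean), ") is at or below the lower bound; ",
         "delta is undefined there", call. = FALSE)
  }
  if (!is.null(b$upper) && b$upper - mean <= tol * scale) {
    stop("mean (", format(mean), ") is at or above the upper bound; ",
         "delta is undefined there", call. = FALSE)
  }
  invisible(TRUE)
}
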
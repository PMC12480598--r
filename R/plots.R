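#' Plot mean-bias curves of heterogeneity measures
#'
#' One panel per measure, value against the mean at fixed dispersion. The
#' delta panel is flat; every other panel shows that measure's
#' mean-dependence.
#'
#' @param curves A long tibble from [bias_curve()].
#' @return A ggplot object.
#' @export
plot_bias_curves <- function(curves) {
  stopifnot(all(c("mean", "measure", "value") %in% names(curves)))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$mean, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(x = "mean", y = "measure value",
                  title = "Mean-dependence of heterogeneity measures at fixed dispersion") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bias_curve_df <- function(object, ...) plot_bias_curves(object)

#' Plot the warped heterogeneity-diversity relationship
#'
#' Richness against one heterogeneity measure across a warp grid, coloured
#' by the true dispersion. Mean-biased measures fold the rectangular
#' (mean, dispersion) lattice into a curved sheet whose envelope reads as a
#' hump; the delta measure leaves the lattice unwarped.
#'
#' @param grid A tibble from [make_warp_grid()].
#' @param measure Column to put on the x axis (e.g. `"range"`, `"delta"`).
#' @return A ggplot object.
#' @export
plot_warp_grid <- function(grid, measure = "range") {
  stopifnot(measure %in% names(grid))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data[[measure]], y = .data$richness,
                                     colour = .data$delta)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::labs(x = measure, y = "richness", colour = "true delta",
                  title = "Observed HDR under one heterogeneity measure") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hdr_fit <- function(object, ...) {
  d <- stats::model.frame(object$fit)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$m, y = .data$y)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = stats::fitted(object$fit)),
                       colour = "grey40") +
    ggplot2::labs(x = sub("^quadratic:", "", object$tag), y = "richness",
                  title = paste("Quadratic HDR fit,", object$tag)) +
    ggplot2::theme_minimal()
}
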
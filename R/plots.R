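#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a decomposition
#'
#' Stacked panels of the original series, trend and fluctuation.
#'
#' @param object a `decomposition`.
#' @param timestamps optional x-axis values; defaults to the sample index.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot decomposition
#' @export
autoplot.decomposition <- function(object, timestamps = NULL, ...) {
  n <- length(object$trend)
  t <- timestamps %||% seq_len(n)
  df <- tibble::tibble(
    t = rep(t, 3),
    value = c(reconstruct(object), object$trend, object$fluctuation),
    component = factor(rep(c("series", "trend", "fluctuation"), each = n),
                       levels = c("series", "trend", "fluctuation"))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s %s decomposition",
                                  object$mode, object$method))
}

#' Plot a q-Gaussian fit against the empirical density
#'
#' Histogram of the fitted sample (log-scaled density axis, where the
#' power-law tails of a q-Gaussian are straightest) with the fitted
#' density overlaid.
#'
#' @param object a `qgauss_fit`.
#' @param x the sample the fit was computed on.
#' @param bins histogram bin count.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot qgauss_fit
#' @export
autoplot.qgauss_fit <- function(object, x, bins = 80, ...) {
  grid <- seq(min(x), max(x), length.out = 400)
  dens <- tibble::tibble(x = grid, d = dqgauss(grid, object$params))
  ggplot2::ggplot(tibble::tibble(x = x), ggplot2::aes(.data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = NA) +
    ggplot2::geom_line(data = dens, ggplot2::aes(.data$x, .data$d),
                       colour = "purple") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "fluctuation", y = "density",
                  title = sprintf("q-Gaussian fit: q = %.2f, beta = %.3g",
                                  object$params$q, object$params$beta))
}

#' Plot fitted parameters against distance to sea
#'
#' @param object a `distance_trend`.
#' @param records the site records the trend was fitted on.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot distance_trend
#' @export
autoplot.distance_trend <- function(object, records, ...) {
  ggplot2::ggplot(records, ggplot2::aes(.data$dist_to_sea_km,
                                        .data[[object$param]])) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "distance to sea (km)", y = object$param,
                  title = sprintf("%s vs distance: slope %.3g/km, r = %.2f",
                                  object$param, object$slope,
                                  object$correlation))
}

#' Plot per-horizon forecast errors
#'
#' @param report tibble from [evaluate_forecast()] or
#'   [evaluate_baselines()].
#' @param metric `"smape"` or `"mae"`.
#' @return a ggplot object.
#' @export
plot_forecast_errors <- function(report, metric = c("smape", "mae")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(report, ggplot2::aes(.data$horizon, .data[[metric]],
                                       colour = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "horizon (15-min steps)",
                  y = if (metric == "smape") "SMAPE (%)" else "MAE (mg/L)")
}
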
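#' Plot observed versus model-implied RT quantiles
#'
#' One panel per item; points on the identity line indicate that the fitted
#' diffusion model reproduces the observed response-time distribution.
#'
#' @param object A `diffirt_qq` table from [qq_diagnostic()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.diffirt_qq <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$model, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::facet_wrap(~item_id, scales = "free") +
    ggplot2::labs(x = "Model-implied quantile (s)",
                  y = "Observed quantile (s)",
                  title = "Diffusion IRT response-time Q-Q diagnostic") +
    ggplot2::theme_minimal()
}

#' Plot a fitted negative exponential practice curve
#'
#' Observed per-occasion sample means with the fitted population trajectory.
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.growth_fit <- function(object, ...) {
  if (is.null(object$occasion_means)) {
    abort("No occasion means stored for this fit.")
  }
  df <- tidyr::pivot_longer(object$occasion_means, c("observed", "fitted"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$occasion, y = .data$value,
                                   colour = .data$series,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$series == "observed", ], size = 1) +
    ggplot2::labs(x = "Occasion (scheduled order, 0-based)",
                  y = object$variable,
                  title = sprintf("Negative exponential growth: gain %.2f, rate %.2f",
                                  object$gain, object$rate)) +
    ggplot2::theme_minimal()
}

#' Histogram of a score variable with a normal reference curve
#'
#' @param data A data frame of occasion scores.
#' @param var Column to plot (bare name or string).
#' @param bins Histogram bins (default 40).
#' @return A ggplot.
#' @export
plot_score_distribution <- function(data, var, bins = 40) {
  var <- rlang::as_name(rlang::ensym(var))
  x <- data[[var]]
  x <- x[is.finite(x)]
  ggplot2::ggplot(data.frame(x = x), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey40") +
    ggplot2::stat_function(fun = dnorm,
                           args = list(mean = mean(x), sd = sd(x)),
                           colour = "steelblue") +
    ggplot2::labs(x = var, y = "Density") +
    ggplot2::theme_minimal()
}
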
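# Convenience ggplot2 views of each result type. Plots are a reading aid;
# the CSV tables are the analysis surface.

#' Plot monthly trait means against an environmental gradient
#'
#' One panel per trait: monthly population means (points) over the chosen
#' environmental variable, the visual counterpart of the reaction-norm
#' classification.
#'
#' @param trait_means Long tibble from [monthly_trait_means()].
#' @param environment Monthly environment tibble with `month` and the
#'   `env_var` column.
#' @param env_var Environment column to plot against
#'   (default `"mean_temperature"`).
#' @return A ggplot object.
#' @export
plot_reaction_norms <- function(trait_means, environment,
                                env_var = "mean_temperature") {
  check_columns(trait_means, c("month", "trait", "mean"), "trait_means")
  check_columns(environment, c("month", env_var), "environment")
  d <- dplyr::inner_join(trait_means, environment, by = "month")
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[env_var]], y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", se = FALSE, formula = y ~ x,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = env_var, y = "monthly population mean")
}

#' Plot the seasonal course of monthly trait means
#'
#' @param trait_means Long tibble from [monthly_trait_means()].
#' @return A ggplot object (one panel per trait, ribbon = +/- 1 SD).
#' @export
plot_seasonal_traits <- function(trait_means) {
  check_columns(trait_means, c("month", "trait", "mean"), "trait_means")
  d <- dplyr::mutate(trait_means,
                     month_date = as.Date(paste0(.data$month, "-15")))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$month_date,
                                       y = .data$mean)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "monthly mean")
  if ("sd" %in% names(d)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      alpha = 0.15, colour = NA)
  }
  p
}

#' Plot the latitudinal meta-analysis rows
#'
#' PPI against absolute latitude and TAR, and intensity against TAR,
#' coloured by zone — the three standard views of the cross-population
#' comparison.
#'
#' @param rows Tibble from [population_ppi()].
#' @param x One of `"abs_latitude"`, `"tar"`.
#' @param y One of `"ppi_pct"`, `"intensity_pct_per_c"`.
#' @return A ggplot object.
#' @export
plot_latitudinal <- function(rows, x = "tar", y = "intensity_pct_per_c") {
  check_columns(rows, c(x, y, "zone"), "rows")
  ggplot2::ggplot(rows, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                     colour = .data$zone)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = x, y = y, colour = NULL)
}

#' Plot a through-origin contrast regression
#'
#' Standardized response contrasts against standardized predictor
#' contrasts with the fitted through-origin line.
#'
#' @param object An `origin_fit` from [origin_regression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot origin_fit
#' @export
autoplot.origin_fit <- function(object, ...) {
  ggplot2::ggplot(object$contrasts,
                  ggplot2::aes(x = .data$u, y = .data$w)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = object$slope,
                         colour = "grey40") +
    ggplot2::labs(x = "standardized predictor contrast",
                  y = "standardized response contrast",
                  subtitle = sprintf("slope = %.3f, r = %.3f, n = %d",
                                     object$slope, object$r,
                                     object$n_valid))
}
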
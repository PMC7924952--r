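#' Plot a cumulative mortality curve
#'
#' @param object An `msm_mortality_curve` from
#'   [cumulative_mortality_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msm_mortality_curve <- function(object, ...) {
  start <- attr(object, "start_state")
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$mortality)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x),
                                limits = c(0, NA)) +
    ggplot2::labs(
      x = "Years since state entry", y = "Cumulative mortality",
      title = paste0("Mortality from state: ", state_labels()[start])
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of per-transition hazard ratios
#'
#' @param fit An `msm_fit` or a coefficient tibble (see
#'   [hazard_ratio_table()]).
#' @param conf.level Confidence level for the intervals.
#' @return A ggplot.
#' @export
plot_hazard_ratios <- function(fit, conf.level = 0.95) {
  tab <- hazard_ratio_table(fit, conf.level = conf.level)
  ggplot2::ggplot(tab, ggplot2::aes(.data$hr, .data$transition,
                                    colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$term)) +
    ggplot2::labs(x = "Hazard ratio (log scale)", y = NULL,
                  colour = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' Observed-vs-predicted calibration plot
#'
#' @param tab A [calibration_table()] result.
#' @return A ggplot.
#' @export
plot_calibration <- function(tab) {
  ggplot2::ggplot(tab, ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Model-predicted exit probability",
                  y = "Observed (Kaplan-Meier)") +
    ggplot2::theme_minimal()
}
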
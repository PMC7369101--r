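#' Plot cohort state occupancy over time
#'
#' @param object A `cohort_trajectory`.
#' @param ... Unused.
#' @return A ggplot of occupancy per state by model year.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_trajectory <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Model year", y = "Persons",
                  colour = "State",
                  title = "Simulated cohort over the model horizon") +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param object A `psa_result`.
#' @param ... Unused.
#' @return A ggplot of the probability of cost-effectiveness against
#'   willingness to pay.
#' @exportS3Method ggplot2::autoplot
autoplot.psa_result <- function(object, ...) {
  ggplot2::ggplot(object$ceac,
                  ggplot2::aes(x = .data$lambda, y = .data$prob_ce)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$wtp, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (SEK per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Incremental cost-effectiveness scatter of PSA iterations
#'
#' @param result A `psa_result`.
#' @param wtp Willingness-to-pay line to draw, SEK per QALY.
#' @return A ggplot of incremental QALYs vs incremental costs.
#' @export
plot_psa_scatter <- function(result, wtp = result$wtp) {
  ggplot2::ggplot(result$iterations,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(intercept = 0, slope = wtp, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Incremental QALYs per person",
                  y = "Incremental cost per person (SEK)",
                  title = "PSA incremental cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
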
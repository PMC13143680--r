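#' Plot a decision curve
#'
#' Net benefit of the model against the treat-all and treat-none strategies
#' over the threshold-probability range.
#'
#' @param object a `dca_curve` from [decision_curve()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot dca_curve
#' @export
autoplot.dca_curve <- function(object, ...) {
  df <- object |>
    pivot_longer(c("nb_model", "nb_all", "nb_none"),
                 names_to = "strategy", values_to = "net_benefit") |>
    mutate(strategy = dplyr::recode(.data$strategy, nb_model = "model",
                                    nb_all = "treat all",
                                    nb_none = "treat none"))
  ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$net_benefit,
                                   colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, NA)) +
    ggplot2::labs(x = "threshold probability", y = "net benefit",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot OPLS-DA scores
#'
#' Predictive score against the first orthogonal score (or sample index when
#' no orthogonal component exists), coloured by class.
#'
#' @param object an `opls_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot opls_model
#' @export
autoplot.opls_model <- function(object, ...) {
  df <- tibble(t_pred = object$scores,
               t_orth = if (!is.null(object$scores_orth))
                 object$scores_orth[, 1] else seq_along(object$scores),
               class = factor(object$y))
  ggplot2::ggplot(df, ggplot2::aes(.data$t_pred, .data$t_orth,
                                   colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "predictive score", y = "orthogonal score") +
    ggplot2::theme_minimal()
}

#' Plot a Monte-Carlo projection
#'
#' Projected event rate per stratum with its percentile interval.
#'
#' @param object an `mc_projection` from [monte_carlo_projection()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mc_projection
#' @export
autoplot.mc_projection <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$stratum, .data$projected_rate)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::labs(x = NULL, y = "projected event rate") +
    ggplot2::theme_minimal()
}

#' Plot a foam decay trajectory with its fitted half-life
#'
#' @param trajectory tibble from [foam_height_trajectory()].
#' @param fit optional half-life fit from [estimate_half_life()]; computed
#'   when omitted.
#' @return a ggplot object.
#' @export
plot_foam_decay <- function(trajectory, fit = NULL) {
  fit <- fit %||% estimate_half_life(trajectory)
  curve_df <- tibble(time_s = seq(0, max(trajectory$time_s), length.out = 100))
  curve_df$height_mm <- fit$h0_mm * 2^(-curve_df$time_s / fit$t_half_s)
  lab <- if (fit$censored) sprintf("T1/2 > %.0f s", max(trajectory$time_s))
         else sprintf("T1/2 = %.1f s", fit$t_half_s)
  ggplot2::ggplot(trajectory, ggplot2::aes(.data$time_s, .data$height_mm)) +
    ggplot2::geom_line(data = curve_df, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::annotate("text", x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
                      label = lab) +
    ggplot2::labs(x = "time (s)", y = "foam height (mm)") +
    ggplot2::theme_minimal()
}
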
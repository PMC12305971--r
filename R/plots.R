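#' Agreement scatter of board assessments versus predictions
#'
#' Reproduces the board-versus-prediction scatter layout: board value on
#' the abscissa, patient-level model prediction on the ordinate, one panel
#' per model family and dataset, with the identity line.
#'
#' @param object an `sms_evaluation`.
#' @param target which target to plot (default `"sms"`).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot sms_evaluation
#' @export
autoplot.sms_evaluation <- function(object, target = "sms", ...) {
  df <- object$scatter[object$scatter$target == target, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$board, y = .data$prediction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_grid(family ~ dataset) +
    ggplot2::labs(
      x = "expert board assessment",
      y = "patient-level prediction",
      title = paste("Board agreement:", target)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of a feature-importance ranking
#'
#' @param importance tibble from [permutation_importance()] or
#'   [dt_importance()].
#' @param top_n how many top features to show (default 20).
#' @return a ggplot object.
#' @export
plot_importance <- function(importance, top_n = 20L) {
  df <- utils::head(importance[importance$importance > 0, ], top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "importance", y = NULL) +
    ggplot2::theme_minimal()
}

#' Spaghetti plot of simulated angle traces
#'
#' @param cohort an `sms_cohort`.
#' @param angle one of [sms_angles()] (default knee flexion).
#' @param patients optional subset of patient ids.
#' @return a ggplot object.
#' @export
plot_angle_traces <- function(cohort, angle = "knee_flexion",
                              patients = NULL) {
  df <- cohort$angles
  if (!is.null(patients)) df <- df[df$patient_id %in% patients, ]
  df$trace_id <- paste(df$patient_id, df$side, df$stride)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct, y = .data[[angle]],
                                   group = .data$trace_id,
                                   colour = .data$side)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "% gait cycle", y = paste(angle, "(deg)")) +
    ggplot2::theme_minimal()
}
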
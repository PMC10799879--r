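#' Plot a calibration table
#'
#' Observed event fraction per score bin (with exact binomial intervals)
#' against the logistic reference curve, one colour per subgroup, on a
#' log-scaled probability axis.
#'
#' @param object A `risk_calibration` from [calibration()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_calibration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center, y = .data$observed,
                                       colour = .data$subgroup)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           linewidth = 0.3, width = 0.1) +
    ggplot2::stat_function(fun = function(x) plogis(x), colour = "black",
                           linewidth = 0.4, inherit.aes = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "model score (log-odds)", y = "observed event fraction",
                  colour = "subgroup", size = "n") +
    ggplot2::theme_minimal()
}

#' Plot concentration-of-risk strata
#'
#' @param object A `risk_strata` from [concentration_of_risk()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_strata <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$q), y = .data$concentration,
                                       fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "top score fraction", y = "concentration of risk",
                  fill = "outcome component") +
    ggplot2::theme_minimal()
}

#' Plot ensemble coefficients
#'
#' Bar chart of the fine-tuned stacking coefficients, split into base-model
#' amplitudes and fine-tuning covariates. The usage coefficient is shown
#' multiplied by 100 for comparability with the binary covariates (the raw
#' usage index spans hundreds of units while indicators span one).
#'
#' @param object A `risk_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_ensemble <- function(object, ...) {
  td <- tidy(object) |>
    filter(.data$term != "(Intercept)") |>
    mutate(estimate = ifelse(.data$term == "usage", .data$estimate * 100,
                             .data$estimate),
           term = ifelse(.data$term == "usage", "100 x usage", .data$term))
  ggplot2::ggplot(td, ggplot2::aes(x = stats::reorder(.data$term, .data$estimate),
                                   y = .data$estimate, fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "logistic coefficient", fill = NULL,
                  title = paste("Ensemble fine-tuning:", object$target)) +
    ggplot2::theme_minimal()
}

#' Score histograms for cases and controls
#'
#' Normalized score distributions by outcome status (optionally by outcome
#' component), the companion view to a calibration curve.
#'
#' @param scores Risk scores (log-odds).
#' @param labels 0/1 labels or a component factor (`none` treated as control).
#' @param binwidth Histogram bin width in score units.
#' @return A ggplot object.
#' @export
plot_score_histogram <- function(scores, labels, binwidth = 0.5) {
  grp <- if (all(labels %in% c(0, 1))) {
    ifelse(labels == 1, "case", "control")
  } else {
    as.character(labels)
  }
  df <- tibble(score = scores, group = grp)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = ggplot2::after_stat(density),
                                   fill = .data$group)) +
    ggplot2::geom_histogram(binwidth = binwidth, alpha = 0.5,
                            position = "identity") +
    ggplot2::labs(x = "model score (log-odds)", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}
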
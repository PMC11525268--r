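# ggplot2 displays for the main result types.

#' Plot an observer's accuracy curve
#'
#' Accuracy against dot numerosity (log x-axis) at a fixed coherence — the
#' inverted-U signature of stochastic resonance when the pooled signal is
#' sub-threshold.
#'
#' @param params an [observer_params()].
#' @param coherence coherence fraction.
#' @param levels numerosity levels.
#' @return a ggplot.
#' @export
plot_accuracy_curve <- function(params, coherence,
                                levels = sr_dot_levels()) {
  curve <- accuracy_curve(params, coherence, levels)
  ggplot2::ggplot(curve, ggplot2::aes(.data$n_dots, .data$p_correct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "dot numerosity (log scale)", y = "p(correct)",
      title = sprintf("Observer accuracy at %.1f%% coherence",
                      100 * coherence)
    )
}

#' @describeIn staircase_log Trajectory plot of a staircase run, marking
#'   reversals.
#' @param x a `staircase_state`.
#' @param ... ignored.
#' @method autoplot staircase_state
#' @export
autoplot.staircase_state <- function(x, ...) {
  log <- staircase_log(x)
  ggplot2::ggplot(log, ggplot2::aes(.data$trial, .data$coherence_pct)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = dplyr::filter(log, .data$is_reversal),
      colour = "red", size = 2
    ) +
    ggplot2::labs(x = "trial", y = "coherence (%)",
                  title = "1-up-2-down staircase (reversals in red)")
}

#' @describeIn generate_dataset Threshold-vs-age display of a dataset,
#'   coloured by staircase group.
#' @param x an `sr_dataset`.
#' @param ... ignored.
#' @method autoplot sr_dataset
#' @export
autoplot.sr_dataset <- function(x, ...) {
  keep <- dplyr::filter(x$participants, !.data$excluded)
  ggplot2::ggplot(
    keep,
    ggplot2::aes(.data$age, log(.data$threshold_pct),
                 colour = factor(.data$group_dots))
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "age (years)", y = "ln threshold (%)",
                  colour = "staircase dots")
}

#' @describeIn fit_logistic_glmm Predicted accuracy curves at reference
#'   ages (continuous fits) or for both groups (group fits).
#' @param x an `sr_glmm`.
#' @param ages ages to display for continuous fits.
#' @param ... ignored.
#' @method autoplot sr_glmm
#' @export
autoplot.sr_glmm <- function(x, ages = c(20, 40, 60, 80), ...) {
  grid <- exp(seq(log(20), log(2000), length.out = 200))
  keys <- if (x$design$age_meta$mode == "continuous") {
    ages
  } else {
    c("younger", "older")
  }
  pred <- purrr::map_dfr(keys, function(a) predict_accuracy(x, a, grid))
  ggplot2::ggplot(
    pred,
    ggplot2::aes(.data$n_dots, .data$p_correct,
                 colour = factor(.data$age), group = factor(.data$age))
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dot numerosity (log scale)", y = "p(correct)",
                  colour = "age")
}
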
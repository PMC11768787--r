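#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_abline geom_col geom_errorbar labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a recording's axes over time
#'
#' @param object A [recording()].
#' @param from,to Optional time range (seconds).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pn_recording
#' @export
autoplot.pn_recording <- function(object, from = NULL, to = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(from)) df <- df[df$time_s >= from, ]
  if (!is.null(to)) df <- df[df$time_s <= to, ]
  long <- tidyr::pivot_longer(df, cols = c("acc_x", "acc_y", "acc_z"),
                              names_to = "axis", values_to = "acc_g")
  ggplot(long, aes(x = .data$time_s, y = .data$acc_g,
                   colour = .data$axis)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = "acceleration (g)",
         title = sprintf("Subject %s (%g Hz)", attr(object, "subject_id"),
                         attr(object, "rate_hz"))) +
    theme_minimal()
}

#' Plot per-fold LOSO metrics
#'
#' @param object A `pn_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pn_evaluation
#' @export
autoplot.pn_evaluation <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds,
                              cols = c("sensitivity", "specificity", "auroc"),
                              names_to = "metric", values_to = "value")
  long <- long[!is.na(long$value), , drop = FALSE]
  ggplot(long, aes(x = .data$subject_id, y = .data$value)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~metric, ncol = 1L) +
    labs(x = "held-out subject", y = NULL,
         title = sprintf("LOSO metrics (%s)", object$config$model)) +
    theme_minimal()
}

#' Plot a learning curve
#'
#' @param object A `pn_learning_curve` from [learning_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pn_learning_curve
#' @export
autoplot.pn_learning_curve <- function(object, ...) {
  s <- attr(object, "summary")
  ggplot(s, aes(x = .data$duration_min, y = .data$auroc_mean)) +
    geom_ribbon(aes(ymin = .data$auroc_mean - .data$auroc_sd,
                    ymax = .data$auroc_mean + .data$auroc_sd),
                alpha = 0.2) +
    geom_line() +
    geom_point() +
    labs(x = "training data per fold (min)", y = "mean AUROC",
         title = "Learning curve (cumulative sampling)") +
    theme_minimal()
}

#' Plot duration agreement
#'
#' Predicted against annotated tremor seconds per subject, with the
#' identity line marking perfect agreement.
#'
#' @param evaluation A `pn_evaluation`.
#' @return A ggplot object.
#' @export
plot_duration_agreement <- function(evaluation) {
  f <- evaluation$folds
  f <- f[f$true_tremor_s > 0, , drop = FALSE]
  lab <- if (!is.null(evaluation$agreement)) {
    sprintf("ICC %.2f (80%% CI %.2f-%.2f), Pearson R %.2f",
            evaluation$agreement$icc$icc, evaluation$agreement$icc$lower,
            evaluation$agreement$icc$upper, evaluation$agreement$pearson$r)
  } else {
    NULL
  }
  ggplot(f, aes(x = .data$true_tremor_s, y = .data$predicted_tremor_s)) +
    geom_abline(slope = 1, intercept = 0, colour = "red") +
    geom_point(size = 2) +
    labs(x = "annotated tremor (s)", y = "predicted tremor (s)",
         subtitle = lab) +
    theme_minimal()
}
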
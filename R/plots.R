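#' Reliability diagram
#'
#' Observed progression frequency against mean predicted probability per
#' bin, with binomial error bars and the identity line of perfect
#' calibration. Point size reflects bin occupancy.
#'
#' @param object an `ms_reliability` from [reliability_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ms_reliability <- function(object, ...) {
  ggplot(object, aes(x = .data$mean_score, y = .data$obs_freq)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    geom_errorbar(
      aes(
        ymin = pmax(.data$obs_freq - 1.96 * .data$se, 0),
        ymax = pmin(.data$obs_freq + 1.96 * .data$se, 1)
      ),
      width = 0.01, colour = "steelblue"
    ) +
    geom_point(aes(size = .data$n), colour = "steelblue") +
    scale_size_area(max_size = 4, guide = "none") +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(
      x = "Mean predicted probability",
      y = "Observed progression frequency",
      title = "Reliability diagram"
    ) +
    theme_minimal()
}

#' Permutation-importance plot
#'
#' Horizontal bars of mean ROC-AUC degradation per shuffled variable,
#' largest on top.
#'
#' @param object an `ms_importance` from [permutation_importance()].
#' @param top_n number of variables shown.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ms_importance <- function(object, top_n = 20, ...) {
  df <- head(object, top_n)
  ggplot(df, aes(
    x = .data$d_roc_auc,
    y = stats::reorder(.data$feature, .data$d_roc_auc)
  )) +
    geom_col(fill = "steelblue") +
    geom_errorbarh(
      aes(
        xmin = .data$d_roc_auc - .data$sd_roc_auc,
        xmax = .data$d_roc_auc + .data$sd_roc_auc
      ),
      height = 0.3, colour = "grey30"
    ) +
    labs(
      x = "ROC-AUC degradation when shuffled", y = NULL,
      title = "Permutation feature importance"
    ) +
    theme_minimal()
}

#' Benchmark summary plot
#'
#' Mean and standard deviation over repeats of each metric, per model.
#'
#' @param object an `ms_report` from [run_benchmark()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ms_report <- function(object, ...) {
  df <- object$metrics |>
    pivot_longer(c("roc_auc", "auc_pr", "brier", "ece"),
      names_to = "metric", values_to = "value"
    )
  ggplot(df, aes(x = .data$model, y = .data$value, colour = .data$model)) +
    stat_summary(fun = mean, geom = "point", size = 2) +
    stat_summary(fun.data = ggplot2::mean_sdl, fun.args = list(mult = 1), geom = "errorbar", width = 0.2) +
    facet_wrap(~metric, scales = "free_y") +
    guides(colour = "none") +
    labs(x = NULL, y = NULL, title = "External-validation performance") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}
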
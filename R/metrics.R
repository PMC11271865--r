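check_binary <- function(labels) {
  u <- unique(labels[!is.na(labels)])
  if (!all(u %in% c(0, 1))) {
    abort("labels must be 0/1", class = "msprog_metric_error")
  }
  if (length(u) < 2) {
    abort("metric undefined: only one class present",
      class = "msprog_metric_error"
    )
  }
}

#' Area under the ROC curve
#'
#' Pairwise concordance probability with the tie correction (ties count
#' one half), computed from rank sums — identical to the trapezoidal area
#' under the empirical ROC curve.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return value in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_binary(labels)
  labels <- as.integer(labels)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1L)
  n0 <- length(labels) - n1
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision: the mean of precision values at each recall step,
#' walking the ranking from the highest score down. Tied scores are treated
#' as one block (precision evaluated at the block boundary). The chance
#' level equals the positive-class prevalence.
#'
#' @inheritParams roc_auc
#' @return value in `[0, 1]`.
#' @export
auc_pr <- function(scores, labels) {
  check_binary(labels)
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  cum_tp <- cumsum(y)
  n <- length(y)
  # block ends: last index of each tied-score run
  block_end <- which(c(s[-n] != s[-1], TRUE))
  tp <- cum_tp[block_end]
  prec <- tp / block_end
  d_tp <- diff(c(0, tp))
  sum(prec * d_tp) / sum(y)
}

#' Brier score
#'
#' Mean squared difference between the predicted probability and the binary
#' outcome; a proper scoring rule sensitive to both discrimination and
#' calibration.
#'
#' @inheritParams roc_auc
#' @return value in `[0, 1]`.
#' @export
brier <- function(scores, labels) {
  stopifnot(all(scores >= 0 & scores <= 1))
  mean((scores - as.numeric(labels))^2)
}

#' Expected calibration error
#'
#' Partitions `[0, 1]` into `bins` equal-width bins, and averages the
#' absolute gap between mean predicted probability and observed label
#' frequency per bin, weighted by bin occupancy. Empty bins are skipped.
#'
#' @inheritParams roc_auc
#' @param bins number of equal-width bins (20 by default).
#' @return value in `[0, 1]`.
#' @export
ece <- function(scores, labels, bins = 20) {
  stopifnot(all(scores >= 0 & scores <= 1))
  labels <- as.numeric(labels)
  b <- pmin(pmax(ceiling(scores * bins), 1L), bins)
  n <- length(scores)
  tot <- 0
  for (bi in unique(b)) {
    in_b <- b == bi
    tot <- tot + sum(in_b) / n * abs(mean(labels[in_b]) - mean(scores[in_b]))
  }
  tot
}

#' Reliability curve
#'
#' Per-bin mean predicted probability, observed frequency and count, for
#' calibration diagrams.
#'
#' @inheritParams ece
#' @return tibble of class `ms_reliability` with columns `bin`,
#'   `mean_score`, `obs_freq`, `n`, `se` (binomial standard error).
#' @export
reliability_curve <- function(scores, labels, bins = 20) {
  stopifnot(all(scores >= 0 & scores <= 1))
  labels <- as.numeric(labels)
  b <- pmin(pmax(ceiling(scores * bins), 1L), bins)
  out <- tibble(bin = b, score = scores, label = labels) |>
    group_by(.data$bin) |>
    summarise(
      mean_score = mean(.data$score),
      obs_freq = mean(.data$label),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(se = sqrt(pmax(.data$obs_freq * (1 - .data$obs_freq), 1e-12) / .data$n))
  class(out) <- c("ms_reliability", class(out))
  out
}

all_metrics <- function(scores, labels, bins = 20) {
  tibble(
    roc_auc = roc_auc(scores, labels),
    auc_pr = auc_pr(scores, labels),
    brier = brier(scores, labels),
    ece = ece(scores, labels, bins)
  )
}
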
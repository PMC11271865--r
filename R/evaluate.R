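#' Center-level train/validation/test split
#'
#' Whole clinical centers are assigned to one of train, validation or test,
#' so that the validation and test sets are external: models are tuned and
#' evaluated on patients from centers never seen in training. Assignment is
#' greedy over a seeded random center order, targeting the patient-count
#' fractions.
#'
#' @param cohort an `ms_cohort` (or any tibble with `patient_id` and
#'   `center_id` columns, e.g. an episode table).
#' @param fractions length-3 numeric, target patient fractions for
#'   train/validation/test (default 60/20/20).
#' @param seed integer seed; the assignment is deterministic given it.
#' @return tibble of class `ms_split`: `center_id`, `set`
#'   (train/validation/test), `n_patients`.
#' @export
split_by_center <- function(cohort, fractions = c(0.6, 0.2, 0.2), seed = 0) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  pats <- if (inherits(cohort, "ms_cohort")) cohort$patients else as_tibble(cohort)
  sizes <- pats |>
    distinct(.data$patient_id, .data$center_id) |>
    count(.data$center_id, name = "n_patients")
  if (nrow(sizes) < 3) {
    abort("at least 3 centers are required for a center-level split",
      class = "msprog_split_error"
    )
  }
  n_total <- sum(sizes$n_patients)
  sets <- c("train", "validation", "test")
  assigned <- with_seed(seed, {
    ord <- sample.int(nrow(sizes))
    filled <- c(train = 0, validation = 0, test = 0)
    out <- character(nrow(sizes))
    for (ci in ord) {
      deficit <- fractions * n_total - filled
      pick <- sets[which.max(deficit)]
      out[ci] <- pick
      filled[pick] <- filled[pick] + sizes$n_patients[ci]
    }
    out
  })
  res <- mutate(sizes, set = assigned, .after = "center_id")
  # guarantee non-empty validation/test even under extreme size skew
  for (s in sets) {
    if (!s %in% res$set) {
      donor <- res |>
        count_set_sizes() |>
        filter(.data$n_centers > 1) |>
        slice_max(.data$n, n = 1, with_ties = FALSE)
      cand <- which(res$set == donor$set)
      res$set[cand[which.min(res$n_patients[cand])]] <- s
    }
  }
  class(res) <- c("ms_split", class(res))
  attr(res, "seed") <- seed
  attr(res, "fractions") <- fractions
  res
}

count_set_sizes <- function(res) {
  res |>
    group_by(.data$set) |>
    summarise(n = sum(.data$n_patients), n_centers = dplyr::n(), .groups = "drop")
}

#' Permutation feature importance
#'
#' Shuffles one feature (or a named group of one-hot columns jointly) over
#' the test episodes and measures the degradation of ROC-AUC, AUC-PR and the
#' increase in expected calibration error, averaged over independent
#' permutations. Features are ranked by mean ROC-AUC degradation.
#'
#' @param model a trained `ms_model` (vector-input architectures).
#' @param features test feature tibble (or matrix).
#' @param labels test 0/1 labels.
#' @param groups optional named list mapping a display name to a character
#'   vector of columns permuted jointly; by default every feature column is
#'   its own variable.
#' @param n_shuffles permutations per variable.
#' @param seed integer seed.
#' @return tibble of class `ms_importance`: `feature`, `d_roc_auc`,
#'   `d_auc_pr`, `d_ece`, and their permutation standard deviations, sorted
#'   by decreasing `d_roc_auc`.
#' @export
permutation_importance <- function(model, features, labels, groups = NULL,
                                   n_shuffles = 5, seed = 0) {
  X <- as_feature_input(features)
  y <- as.numeric(labels)
  base_p <- predict_proba(model, X)
  base <- all_metrics(base_p, y)
  if (is.null(groups)) {
    groups <- setNames(as.list(colnames(X)), colnames(X))
  }
  res <- with_seed(seed, {
    rows <- imap(groups, function(cols, nm) {
      d <- matrix(0, n_shuffles, 3)
      for (s in seq_len(n_shuffles)) {
        Xp <- X
        perm <- sample.int(nrow(X))
        Xp[, cols] <- X[perm, cols, drop = FALSE]
        attr(Xp, "layout") <- attr(X, "layout") %||% FEATURE_LAYOUT_VERSION
        p <- predict_proba(model, Xp)
        d[s, ] <- c(
          base$roc_auc - roc_auc(p, y),
          base$auc_pr - auc_pr(p, y),
          ece(p, y) - base$ece
        )
      }
      tibble(
        feature = nm,
        d_roc_auc = mean(d[, 1]), sd_roc_auc = sd(d[, 1]),
        d_auc_pr = mean(d[, 2]), sd_auc_pr = sd(d[, 2]),
        d_ece = mean(d[, 3]), sd_ece = sd(d[, 3])
      )
    })
    list_rbind(rows)
  })
  res <- arrange(res, desc(.data$d_roc_auc))
  class(res) <- c("ms_importance", class(res))
  attr(res, "baseline") <- base
  res
}

#' Metrics per clinical subgroup
#'
#' Slices scored episodes by MS course at baseline, by baseline EDSS
#' (at or below 5.5 versus above), or by center, and computes the four
#' performance metrics per slice. Slices with a single outcome class are
#' flagged `metric_defined = FALSE` (with `NA` discrimination metrics)
#' rather than raising an error — small centers often record no progression.
#'
#' @param predictions numeric scores aligned with `episodes`.
#' @param episodes episode tibble (needs `course_at_t0`, `baseline_edss`,
#'   `center_id`, and the label column).
#' @param grouping `"course"`, `"edss"`, or `"center"`.
#' @param labels optional explicit label vector (defaults to
#'   `episodes$w_c`).
#' @return tibble: group, `n`, `prevalence`, `metric_defined`, `roc_auc`,
#'   `auc_pr`, `brier`, `ece`.
#' @export
subgroup_report <- function(predictions, episodes,
                            grouping = c("course", "edss", "center"),
                            labels = NULL) {
  grouping <- match.arg(grouping)
  y <- as.numeric(labels %||% episodes$w_c)
  grp <- switch(grouping,
    course = episodes$course_at_t0,
    edss = ifelse(episodes$baseline_edss <= 5.5, "EDSS<=5.5", "EDSS>5.5"),
    center = episodes$center_id
  )
  tibble(group = grp, score = predictions, label = y) |>
    group_by(.data$group) |>
    group_modify(function(df, key) {
      defined <- length(unique(df$label)) == 2
      disc <- if (defined) {
        tibble(
          roc_auc = roc_auc(df$score, df$label),
          auc_pr = auc_pr(df$score, df$label)
        )
      } else {
        tibble(roc_auc = NA_real_, auc_pr = NA_real_)
      }
      bind_cols(
        tibble(
          n = nrow(df), prevalence = mean(df$label),
          metric_defined = defined
        ),
        disc,
        tibble(brier = brier(df$score, df$label), ece = ece(df$score, df$label))
      )
    }) |>
    ungroup()
}
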
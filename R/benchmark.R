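#' Configuration of a full benchmark run
#'
#' Bundles everything [run_benchmark()] needs: the cohort source (a
#' [sim_config()] or a directory of cohort CSVs), the episode inclusion
#' threshold `k`, the split fractions and per-repeat seeds, the model
#' specifications, and the calibration method.
#'
#' @param sim a [sim_config()] used to generate the cohort, ignored when
#'   `cohort_dir` is given.
#' @param cohort_dir optional directory with cohort CSV tables
#'   (see [read_cohort()]).
#' @param k minimal number of EDSS measurements in the trailing 3.25 years
#'   (3 or 6).
#' @param fractions train/validation/test patient fractions.
#' @param n_repeats number of independent split-train-evaluate repeats.
#' @param split_seeds integer seeds, one per repeat.
#' @param models named list of [model_spec()]s to benchmark.
#' @param calibration `"auto"`, `"platt"`, `"isotonic"`, or `"none"`.
#' @param importance logical: compute permutation importance for the first
#'   vector-input model on the last repeat's test set.
#' @param importance_shuffles permutations per variable.
#' @return a `ms_run_config` list.
#' @export
run_config <- function(sim = sim_config(), cohort_dir = NULL, k = 3,
                       fractions = c(0.6, 0.2, 0.2), n_repeats = 5,
                       split_seeds = NULL,
                       models = list(
                         mlp = model_spec("mlp"),
                         bayesian_nn = model_spec("bayesian_nn"),
                         temporal_attention = model_spec("temporal_attention")
                       ),
                       calibration = "auto", importance = TRUE,
                       importance_shuffles = 5) {
  split_seeds <- split_seeds %||% seq_len(n_repeats) - 1L
  stopifnot(length(split_seeds) == n_repeats, k >= 1)
  if (!is.null(names(models)) && any(names(models) == "")) {
    abort("all models must be named", class = "msprog_config_error")
  }
  structure(
    list(
      sim = sim, cohort_dir = cohort_dir, k = k, fractions = fractions,
      n_repeats = n_repeats, split_seeds = as.integer(split_seeds),
      models = models, calibration = calibration, importance = importance,
      importance_shuffles = importance_shuffles
    ),
    class = "ms_run_config"
  )
}

#' Run the full progression-prediction benchmark
#'
#' Executes the complete pipeline: obtain the cohort (simulated or from
#' CSVs), clean it, enumerate and label episodes, engineer features, then
#' for each repeat split whole centers into train/validation/test, train
#' every configured model with inverse-prevalence weights, fit post-hoc
#' calibration on validation scores, and evaluate discrimination and
#' calibration on the held-out test centers. Subgroup slices (MS course and
#' baseline EDSS) and permutation feature importance are computed on test
#' data.
#'
#' @param config a [run_config()].
#' @param progress print per-stage progress.
#' @return an `ms_report` object; see [tidy.ms_report()],
#'   [glance.ms_report()], [autoplot.ms_report()], [write_report()].
#' @export
run_benchmark <- function(config = run_config(), progress = interactive()) {
  stopifnot(inherits(config, "ms_run_config"))
  say <- function(...) if (progress) message(sprintf(...))

  say("stage 1/5: cohort")
  cohort <- if (!is.null(config$cohort_dir)) {
    read_cohort(config$cohort_dir)
  } else {
    simulate_cohort(config$sim)
  }
  cohort <- clean_cohort(cohort)

  say("stage 2/5: episodes")
  episodes <- enumerate_episodes(cohort, k = config$k)
  valid <- filter(episodes, .data$valid)
  if (nrow(valid) < 50) {
    abort("fewer than 50 valid episodes; enlarge the cohort",
      class = "msprog_data_error"
    )
  }

  say("stage 3/5: features (%d valid episodes)", nrow(valid))
  feats <- build_dynamic_features(cohort, valid)
  needs_seq <- any(vapply(
    config$models, function(m) m$architecture == "temporal_attention", logical(1)
  ))
  seqs <- if (needs_seq) build_longitudinal_sequences(cohort, valid) else NULL

  per_repeat <- list()
  subgroups <- list()
  calib_choices <- list()
  split_tables <- list()
  last_test <- NULL

  for (r in seq_len(config$n_repeats)) {
    seed_r <- config$split_seeds[r]
    say("stage 4/5: repeat %d/%d (split seed %d)", r, config$n_repeats, seed_r)
    split <- split_by_center(valid, config$fractions, seed = seed_r)
    set_of <- setNames(split$set, split$center_id)
    idx <- split(seq_len(nrow(valid)), set_of[valid$center_id])
    if (any(vapply(idx[c("train", "validation", "test")], function(i) {
      length(unique(valid$w_c[i])) < 2
    }, logical(1)))) {
      abort("a split set contains a single outcome class; enlarge the cohort",
        class = "msprog_split_error"
      )
    }
    split_tables[[r]] <- mutate(split, repeat_index = r - 1L, .before = 1)

    sub <- function(i) feats[i, , drop = FALSE]
    y <- valid$w_c
    w_train <- class_weights(y[idx$train])

    for (mn in names(config$models)) {
      spec0 <- config$models[[mn]]
      spec <- spec0
      spec$seed <- spec0$seed + 1000L * seed_r # independent weights per repeat
      is_seq <- spec$architecture == "temporal_attention"
      model <- train_model(
        spec, sub(idx$train), y[idx$train],
        weights = w_train,
        validation = list(
          features = sub(idx$validation), labels = y[idx$validation],
          sequences = if (is_seq) seqs[idx$validation, ] else NULL
        ),
        sequences = if (is_seq) seqs[idx$train, ] else NULL
      )
      p_val <- predict_proba(
        model, sub(idx$validation),
        sequences = if (is_seq) seqs[idx$validation, ] else NULL
      )
      p_test <- predict_proba(
        model, sub(idx$test),
        sequences = if (is_seq) seqs[idx$test, ] else NULL
      )
      if (config$calibration != "none") {
        cal <- fit_calibration(p_val, y[idx$validation], method = config$calibration)
        p_test <- calibrate_scores(cal, p_test)
        calib_choices[[paste(mn, r)]] <- tibble(
          model = mn, repeat_index = r - 1L, calibration = cal$method,
          val_ece = cal$val_ece
        )
      }
      per_repeat[[paste(mn, r)]] <- bind_cols(
        tibble(model = mn, repeat_index = r - 1L),
        all_metrics(p_test, y[idx$test])
      )
      ep_test <- valid[idx$test, ]
      subgroups[[paste(mn, r, "course")]] <- subgroup_report(p_test, ep_test, "course") |>
        mutate(model = mn, repeat_index = r - 1L, grouping = "course", .before = 1)
      subgroups[[paste(mn, r, "edss")]] <- subgroup_report(p_test, ep_test, "edss") |>
        mutate(model = mn, repeat_index = r - 1L, grouping = "edss", .before = 1)
      if (mn == names(config$models)[1] && !is_seq) {
        last_test <- list(model = model, idx = idx$test)
      }
    }
  }

  importance <- NULL
  if (isTRUE(config$importance) && !is.null(last_test)) {
    say("stage 5/5: permutation importance")
    importance <- permutation_importance(
      last_test$model, feats[last_test$idx, , drop = FALSE],
      valid$w_c[last_test$idx],
      n_shuffles = config$importance_shuffles, seed = 0
    )
  }

  metrics <- list_rbind(per_repeat)
  aggregate <- metrics |>
    group_by(.data$model) |>
    summarise(across(
      c("roc_auc", "auc_pr", "brier", "ece"),
      list(mean = mean, sd = sd)
    ), n_repeats = dplyr::n(), .groups = "drop")

  structure(
    list(
      schema_version = "ms-report-v1",
      n_patients = nrow(cohort$patients),
      n_valid_episodes = nrow(valid),
      prevalence = mean(valid$w_c),
      exclusions = episode_exclusions(episodes),
      k = config$k,
      metrics = metrics,
      aggregate = aggregate,
      subgroups = list_rbind(subgroups),
      calibration = if (length(calib_choices)) list_rbind(calib_choices) else NULL,
      importance = importance,
      splits = list_rbind(split_tables),
      seeds = config$split_seeds
    ),
    class = "ms_report"
  )
}

#' @export
print.ms_report <- function(x, ...) {
  cat(sprintf(
    "<ms_report> %d valid episodes (prevalence %.3f), %d repeat(s)\n",
    x$n_valid_episodes, x$prevalence, length(x$seeds)
  ))
  print(as.data.frame(x$aggregate), digits = 3)
  invisible(x)
}

#' Per-repeat metrics of a benchmark report
#'
#' @param x an `ms_report`.
#' @param ... unused.
#' @return tibble with one row per model and repeat.
#' @export
tidy.ms_report <- function(x, ...) x$metrics

#' Aggregated benchmark summary
#'
#' @param x an `ms_report`.
#' @param ... unused.
#' @return tibble with one row per model: mean and standard deviation over
#'   repeats of ROC-AUC, AUC-PR, Brier score and ECE.
#' @export
glance.ms_report <- function(x, ...) x$aggregate

#' Write a benchmark report to JSON
#'
#' @param report an `ms_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "ms_report"))
  out <- report
  class(out) <- NULL
  out$importance <- if (!is.null(out$importance)) as.data.frame(out$importance)
  jsonlite::write_json(out, path,
    auto_unbox = TRUE, digits = NA, dataframe = "columns", null = "null"
  )
  invisible(path)
}

#' Read a benchmark report back from JSON
#'
#' @param path file written by [write_report()].
#' @return an `ms_report`.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c(
    "metrics", "aggregate", "subgroups", "calibration", "importance",
    "splits", "exclusions"
  )) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- as_tibble(as.data.frame(raw[[nm]]))
  }
  structure(raw, class = "ms_report")
}
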
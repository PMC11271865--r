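test_that("ROC-AUC equals the pairwise concordance count", {
  # perfect and reversed rankings
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  # ties count one half
  expect_equal(roc_auc(c(0.5, 0.5), c(1, 0)), 0.5)
  # against the O(n^2) oracle on random scored sets
  for (seed in 1:5) {
    sl <- sim_scored_labels(400, prevalence = 0.3, signal = 1, seed = seed)
    s <- round(sl$scores, 2) # force ties
    expect_equal(roc_auc(s, sl$labels), bf_roc_auc(s, sl$labels))
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), class = "msprog_metric_error")
  # independent cross-check against an established implementation
  sl <- sim_scored_labels(300, prevalence = 0.4, signal = 1, seed = 9)
  expect_equal(
    roc_auc(sl$scores, sl$labels),
    as.numeric(pROC::auc(pROC::roc(sl$labels, sl$scores, quiet = TRUE)))
  )
})

test_that("average precision has prevalence as its chance level", {
  expect_equal(auc_pr(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1)
  set.seed(1)
  y <- rbinom(20000, 1, 0.11)
  s <- runif(20000)
  expect_equal(auc_pr(s, y), mean(y), tolerance = 0.05)
  expect_equal(roc_auc(s, y), 0.5, tolerance = 0.02)
  # block handling of tied scores: all scores equal -> precision = prevalence
  expect_equal(auc_pr(rep(0.5, 10), c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0)), 0.2)
})

test_that("the Brier score matches its closed forms", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 8), rbinom(8, 1, 0.5)), 0.25)
  # constant predictor p on prevalence-p labels: p(1-p) in expectation,
  # exactly (1-p)p^2 + p(1-p)^2 = p(1-p) for realized prevalence p
  y <- c(rep(1, 3), rep(0, 7))
  expect_equal(brier(rep(0.3, 10), y), 0.3 * 0.7)
})

test_that("ECE matches a hand-built binned fixture", {
  # 40 items in 4 occupied bins of a 20-bin grid
  scores <- c(
    rep(0.025, 10), # bin 1: mean score 0.025
    rep(0.225, 10), # bin 5: mean score 0.225
    rep(0.525, 10), # bin 11
    rep(0.925, 10) # bin 19
  )
  labels <- c(
    rep(c(1, 0, 0, 0, 0), 2), # freq 0.2 -> gap 0.175
    rep(c(1, 1, 0, 0, 0), 2), # freq 0.4 -> gap 0.175
    rep(c(1, 1, 1, 0, 0), 2), # freq 0.6 -> gap 0.075
    rep(c(1, 1, 1, 1, 0), 2) # freq 0.8 -> gap 0.125
  )
  expected <- (10 / 40) * (0.175 + 0.175 + 0.075 + 0.125)
  expect_equal(ece(scores, labels, bins = 20), expected)
  # degenerate extremes
  expect_equal(ece(rep(1, 5), rep(0, 5)), 1)
  expect_equal(ece(rep(0, 5), rep(0, 5)), 0)
  # scores matching in-bin frequencies give zero error
  expect_equal(ece(c(rep(0.5, 4)), c(1, 1, 0, 0), bins = 2), 0)
})

test_that("the reliability curve shares its binning with the ECE", {
  sl <- sim_scored_labels(500, prevalence = 0.3, signal = 1, seed = 3)
  rc <- reliability_curve(sl$scores, sl$labels, bins = 20)
  expect_lte(nrow(rc), 20)
  expect_equal(sum(rc$n), 500)
  recon <- sum(rc$n / 500 * abs(rc$obs_freq - rc$mean_score))
  expect_equal(recon, ece(sl$scores, sl$labels, 20))
  p <- autoplot(rc)
  expect_s3_class(p, "ggplot")
})

test_that("calibrated scores are close to the identity under Platt scaling", {
  set.seed(5)
  p_true <- runif(3000, 0.02, 0.98)
  y <- rbinom(3000, 1, p_true)
  cal <- fit_calibration(p_true, y, method = "platt")
  mid <- seq(0.1, 0.9, by = 0.1)
  expect_equal(calibrate_scores(cal, mid), mid, tolerance = 0.05)
})

test_that("isotonic calibration maps are non-decreasing", {
  set.seed(6)
  s <- runif(500)
  y <- rbinom(500, 1, plogis(3 * (s - 0.5)))
  cal <- fit_calibration(s, y, method = "isotonic")
  out <- calibrate_scores(cal, sort(runif(200)))
  expect_true(all(diff(out) >= -1e-12))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("calibration fitted on validation reduces held-out ECE", {
  # deliberately overconfident scores: true probability = 0.5 * score
  set.seed(7)
  s_val <- runif(2000)
  y_val <- rbinom(2000, 1, 0.5 * s_val)
  s_test <- runif(2000)
  y_test <- rbinom(2000, 1, 0.5 * s_test)
  for (method in c("platt", "isotonic", "auto")) {
    cal <- fit_calibration(s_val, y_val, method = method)
    before <- ece(s_test, y_test)
    after <- ece(calibrate_scores(cal, s_test), y_test)
    expect_lt(after, before)
  }
  expect_error(
    fit_calibration(runif(10), rep(1, 10)),
    class = "msprog_metric_error"
  )
})

test_that("auto calibration selects the lower validation ECE", {
  set.seed(8)
  s <- runif(1500)
  y <- rbinom(1500, 1, 0.5 * s)
  cal <- fit_calibration(s, y, method = "auto")
  expect_equal(cal$val_ece, min(cal$candidates))
  expect_true(cal$method %in% c("platt", "isotonic"))
})

test_that("center splits are exclusive, seeded, and close to the target fractions", {
  coh <- tiny_cohort()$clean
  sp1 <- split_by_center(coh, seed = 3)
  sp2 <- split_by_center(coh, seed = 3)
  expect_identical(sp1$set, sp2$set)
  expect_setequal(sp1$center_id, unique(coh$patients$center_id))
  expect_equal(anyDuplicated(sp1$center_id), 0)
  # under skewed center sizes the achieved patient fractions stay within
  # 5 points of the 60/20/20 targets
  set.seed(42)
  skewed <- tibble::tibble(
    patient_id = sprintf("q%04d", 1:2000),
    center_id = sample(sprintf("c%02d", 1:40), 2000,
      replace = TRUE, prob = exp(rnorm(40, 0, 1.1))
    )
  )
  for (seed in 0:2) {
    sp <- split_by_center(skewed, seed = seed)
    got <- tapply(sp$n_patients, sp$set, sum) / sum(sp$n_patients)
    expect_lt(abs(got[["train"]] - 0.6), 0.05)
    expect_lt(abs(got[["validation"]] - 0.2), 0.05)
    expect_lt(abs(got[["test"]] - 0.2), 0.05)
  }
  expect_error(
    split_by_center(tibble::tibble(patient_id = 1:2, center_id = c("a", "b"))),
    class = "msprog_split_error"
  )
})

test_that("episodes of one patient never straddle split sets", {
  eps <- dplyr::filter(tiny_cohort()$episodes, valid)
  sp <- split_by_center(eps, seed = 1)
  set_of <- setNames(sp$set, sp$center_id)
  by_patient <- tapply(set_of[eps$center_id], eps$patient_id, dplyr::n_distinct)
  expect_true(all(by_patient == 1))
})

test_that("subgroup reports slice exhaustively and flag degenerate groups", {
  eps <- dplyr::filter(tiny_cohort()$episodes, valid)
  set.seed(2)
  p <- runif(nrow(eps))
  rep_edss <- subgroup_report(p, eps, "edss")
  expect_setequal(rep_edss$group, c("EDSS<=5.5", "EDSS>5.5"))
  expect_equal(sum(rep_edss$n), nrow(eps))
  rep_center <- subgroup_report(p, eps, "center")
  expect_equal(sum(rep_center$n), nrow(eps))
  # degenerate slices carry NA discrimination instead of erroring
  if (any(!rep_center$metric_defined)) {
    expect_true(all(is.na(rep_center$roc_auc[!rep_center$metric_defined])))
  }
  one_class <- eps[eps$w_c == 0, ][1:20, ]
  rep1 <- subgroup_report(runif(20), one_class, "course")
  expect_true(all(!rep1$metric_defined))
})

test_that("permutation importance finds signal features and ignores null ones", {
  set.seed(10)
  n <- 1500
  X <- cbind(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * X[, "signal"]))
  idx <- sample(rep(1:3, length.out = n))
  spec <- model_spec("mlp",
    hidden_width = 8, n_hidden_layers = 2,
    max_epochs = 25, patience = 5, batch_size = 64
  )
  m <- train_model(spec, X[idx == 1, ], y[idx == 1],
    validation = list(features = X[idx == 2, ], labels = y[idx == 2])
  )
  imp <- permutation_importance(m, X[idx == 3, ], y[idx == 3],
    n_shuffles = 4, seed = 2
  )
  expect_equal(imp$feature[1], "signal")
  expect_lt(max(abs(imp$d_roc_auc[imp$feature != "signal"])), 0.05)
  expect_gt(imp$d_roc_auc[1], 0.15)
  # reproducible given the seed
  imp2 <- permutation_importance(m, X[idx == 3, ], y[idx == 3],
    n_shuffles = 4, seed = 2
  )
  expect_identical(imp$d_roc_auc, imp2$d_roc_auc)
  expect_s3_class(autoplot(imp), "ggplot")
})
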
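test_that("DMT names map to their efficacy classes", {
  expect_equal(categorize_dmt("Natalizumab"), "high")
  expect_equal(categorize_dmt("Fingolimod"), "moderate")
  expect_equal(categorize_dmt("Mitoxantrone"), "high_induction")
  expect_equal(categorize_dmt("Cyclophosphamide"), "high_induction")
  expect_equal(categorize_dmt("interferons"), "low") # case-insensitive
  expect_equal(
    categorize_dmt(c("Glatiramer", "Rituximab")), c("low", "high")
  )
  expect_error(categorize_dmt("Aspirin"), class = "msprog_vocab_error")
  expect_error(categorize_dmt("Aspirin"), "accepted names")
})

test_that("treatment end dates are imputed at the next DMT start", {
  trt <- tibble::tibble(
    patient_id = "p",
    dmt_name = c("Interferons", "Fingolimod"),
    start_date = as.Date(c("2014-01-01", "2016-01-01")),
    end_date = as.Date(c(NA, NA))
  )
  out <- impute_treatment_ends(trt)
  expect_equal(out$end_date[out$dmt_name == "Interferons"], as.Date("2016-01-01"))
  expect_true(is.na(out$end_date[out$dmt_name == "Fingolimod"]))

  # induction DMTs overlap others and keep start-only semantics
  trt2 <- tibble::tibble(
    patient_id = "p",
    dmt_name = c("Interferons", "Mitoxantrone"),
    start_date = as.Date(c("2014-01-01", "2015-01-01")),
    end_date = as.Date(c(NA, NA))
  )
  out2 <- impute_treatment_ends(trt2)
  expect_true(is.na(out2$end_date[out2$dmt_name == "Interferons"]))
  expect_true(is.na(out2$end_date[out2$dmt_name == "Mitoxantrone"]))

  # a recorded end beyond the next start is clipped: no overlapping
  # non-induction intervals remain
  trt3 <- tibble::tibble(
    patient_id = "p",
    dmt_name = c("Interferons", "Fingolimod"),
    start_date = as.Date(c("2014-01-01", "2016-01-01")),
    end_date = as.Date(c("2017-06-01", NA))
  )
  out3 <- impute_treatment_ends(trt3)
  expect_equal(out3$end_date[out3$dmt_name == "Interferons"], as.Date("2016-01-01"))
})

test_that("the inverse-time transform handles its sentinel cases", {
  expect_equal(inverse_time_transform(NA), 0)
  expect_equal(inverse_time_transform(-0.5), 1)
  expect_equal(inverse_time_transform(0), 1)
  expect_equal(inverse_time_transform(1), 0.5)
  expect_equal(inverse_time_transform(c(NA, -2, 3)), c(0, 1, 0.25))
  t <- c(0, 0.1, 2, 40)
  expect_true(all(inverse_time_transform(t) >= 0 & inverse_time_transform(t) <= 1))
})

test_that("static features encode the baseline state", {
  coh <- make_cohort(
    list(p = data.frame(day = c(-900, -400, 0), edss = c(2, 2.5, 3))),
    courses = tibble::tibble(
      patient_id = "p", course = "RR", effective_date = ORIGIN - 3000
    )
  )
  eps <- enumerate_episodes(coh, k = 3)
  st <- build_static_features(coh, eps[eps$t0 == ORIGIN, ])
  expect_equal(st$edss_t0, 3)
  expect_equal(st$course_RR, 1)
  expect_equal(st$course_SP + st$course_PP, 0)
  expect_equal(st$sex_F, 1)
  expect_equal(st$edu_unknown, 1) # missing education routes to unknown
  expect_equal(st$sym_missing, 1)
  expect_equal(st$dmt_none, 1)
  expect_equal(st$pred_time, as.numeric(ORIGIN - as.Date("1990-01-01")) / 365.25)
  # indicator groups sum to one
  expect_equal(st$sex_F + st$sex_M, 1)
  expect_equal(st$edu_higher + st$edu_no_higher + st$edu_unknown, 1)
  expect_equal(
    st$sym_supratentorial + st$sym_optic_pathways + st$sym_brainstem +
      st$sym_spinal_cord + st$sym_missing, 1
  )
})

test_that("the feature layout is pinned", {
  coh <- tiny_cohort()$clean
  v <- dplyr::filter(tiny_cohort()$episodes, valid)[1:5, ]
  f <- build_dynamic_features(coh, v)
  expect_equal(
    names(f)[1:12],
    c(
      "patient_id", "center_id", "t0", "sex_F", "sex_M", "age", "age_onset",
      "disease_duration", "course_RR", "course_SP", "course_PP", "edss_t0"
    )
  )
  x <- feature_matrix(f)
  expect_equal(ncol(x), 93)
  expect_equal(attr(x, "layout"), "static-dynamic-v1")
  expect_false(any(is.na(x)))
  # transformed times and fractions live in [0, 1]
  for (cn in c(
    "t_since_relapse_tr", "t_first_dmt_tr", "t_first_high_dmt_tr",
    "t_fampridine_tr", "frac_dd_on_dmt"
  )) {
    expect_true(all(x[, cn] >= 0 & x[, cn] <= 1))
  }
  expect_true(all(x[, "edss_std_3y"] >= 0))
})

test_that("dynamic summaries match an independent naive recomputation", {
  coh <- tiny_cohort()$clean
  eps <- dplyr::filter(tiny_cohort()$episodes, valid)
  set.seed(4)
  sub <- eps[sample(nrow(eps), 40), ]
  f <- build_dynamic_features(coh, sub)
  visits <- dplyr::arrange(coh$visits, patient_id, visit_date)
  for (i in seq_len(nrow(sub))) {
    pid <- sub$patient_id[i]
    t0 <- sub$t0[i]
    pv <- visits[visits$patient_id == pid & !is.na(visits$edss), ]
    hist <- pv[pv$visit_date <= t0, ]
    win <- hist[as.numeric(t0 - hist$visit_date) <= 1186, ]
    expect_equal(f$n_visits_3y[i], nrow(win))
    expect_equal(f$edss_min[i], min(hist$edss))
    expect_equal(f$edss_max[i], max(hist$edss))
    expect_equal(f$edss_mean_3y[i], mean(win$edss))
    expect_equal(
      f$edss_std_3y[i], sqrt(mean((win$edss - mean(win$edss))^2))
    )
    expect_equal(f$edss_oldest_3y[i], win$edss[1])
    # one KFS channel, observed values only
    kf <- win$kfs_sensory[!is.na(win$kfs_sensory)]
    if (length(kf) > 0) {
      expect_equal(f$kfs_sensory_mean_3y[i], mean(kf))
      expect_equal(f$kfs_sensory_oldest_3y[i], kf[1])
    } else {
      expect_equal(f$kfs_sensory_mean_3y[i], 0)
    }
    rel <- coh$relapses$onset_date[coh$relapses$patient_id == pid]
    n_rel <- sum(rel <= t0)
    fy <- as.numeric(t0 - pv$visit_date[1]) / 365.25
    expect_equal(f$relapse_rate[i], if (fy > 0) n_rel / fy else 0)
  }
})

test_that("features are invariant to input row order", {
  coh <- tiny_cohort()$clean
  v <- dplyr::filter(tiny_cohort()$episodes, valid)[1:20, ]
  f1 <- build_dynamic_features(coh, v)
  coh2 <- coh
  set.seed(9)
  for (tab in c("visits", "relapses", "treatments", "courses")) {
    coh2[[tab]] <- coh2[[tab]][sample(nrow(coh2[[tab]])), ]
  }
  f2 <- build_dynamic_features(coh2, v)
  expect_equal(as.data.frame(f1), as.data.frame(f2))
})

test_that("longitudinal sequences merge same-date events and track relapses", {
  coh <- make_cohort(
    list(p = data.frame(day = c(-900, -400, -100, 0), edss = c(2, 2.5, 3, 3))),
    relapses = list(p = c(-400, -50))
  )
  eps <- enumerate_episodes(coh, k = 3)
  sq <- build_longitudinal_sequences(coh, eps[eps$t0 == ORIGIN, ])
  m <- sq$seq[[1]]
  # 4 visits + 2 relapses, one on a visit date -> 5 steps
  expect_equal(nrow(m), 5)
  expect_true(all(diff(m[, "time"]) > 0))
  expect_true(all(m[, "time"] <= 0))
  # the merged step carries both the visit and the relapse
  merged <- which(m[, "relapse_occ"] == 1 & m[, "mask_edss"] == 1)
  expect_length(merged, 1)
  expect_equal(unname(m[merged, "edss"]), 2.5)
  # cumulative relapse count is non-decreasing and ends at 2
  expect_true(all(diff(m[, "cum_relapse"]) >= 0))
  expect_equal(m[nrow(m), "cum_relapse"], c(cum_relapse = 2))
  # masks flag unobserved KFS channels
  expect_true(all(m[, "mask_kfs_pyramidal"] == 0))
  # a relapse-only step has no EDSS observation
  solo <- which(m[, "relapse_occ"] == 1 & m[, "mask_edss"] == 0)
  expect_length(solo, 1)
  expect_equal(m[solo, "edss"], c(edss = 0))
})

test_that("dmt channels in the sequence follow the active treatment", {
  trt <- tibble::tibble(
    patient_id = "p", dmt_name = "Fingolimod",
    start_date = ORIGIN - 500, end_date = ORIGIN - 200
  )
  coh <- make_cohort(
    list(p = data.frame(day = c(-900, -400, 0), edss = c(2, 2, 2))),
    treatments = trt
  )
  eps <- enumerate_episodes(coh, k = 3)
  m <- build_longitudinal_sequences(coh, eps[eps$t0 == ORIGIN, ])$seq[[1]]
  # steps: 3 visits + treatment start + treatment end
  expect_equal(nrow(m), 5)
  on <- m[, "dmt_moderate"] == 1
  expect_equal(sum(on), 3) # start, covered visit, end
  expect_true(all(m[!on, "dmt_none"] == 1))
})
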
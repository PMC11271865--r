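# Shared fixture builders and independent oracles. The oracles are written
# as plain loops straight from the clinical definitions, deliberately
# independent of the package's vectorized implementations.

ORIGIN <- as.Date("2010-06-15")

# Build a minimal ms_cohort for one or more patients. `visits` is a list of
# data.frames with columns day (offset from ORIGIN) and edss; relapses a
# list of numeric day offsets.
make_cohort <- function(visits, relapses = NULL, courses = NULL,
                        treatments = NULL, fampridine = NULL,
                        sex = "F", center = "C1",
                        onset_day = -4000, diagnosis_day = -3800,
                        extraction_date = ORIGIN + 8000) {
  ids <- names(visits)
  stopifnot(!is.null(ids))
  pats <- tibble::tibble(
    patient_id = ids,
    center_id = rep_len(center, length(ids)),
    sex = rep_len(sex, length(ids)),
    birth_date = ORIGIN - 11000,
    ms_onset_date = ORIGIN + onset_day,
    diagnosis_date = ORIGIN + diagnosis_day,
    education = NA_character_,
    first_symptom = NA_character_
  )
  vis <- dplyr::bind_rows(lapply(ids, function(id) {
    v <- visits[[id]]
    kfs <- matrix(NA_real_, nrow(v), 8)
    colnames(kfs) <- paste0("kfs_", c(
      "pyramidal", "cerebellar", "brainstem", "sensory",
      "sphincteric", "visual", "cerebral", "ambulatory"
    ))
    dplyr::bind_cols(
      tibble::tibble(
        patient_id = id, visit_date = ORIGIN + v$day, edss = v$edss
      ),
      tibble::as_tibble(kfs)
    )
  }))
  rel <- if (is.null(relapses)) {
    tibble::tibble(patient_id = character(), onset_date = as.Date(character()))
  } else {
    dplyr::bind_rows(lapply(names(relapses), function(id) {
      tibble::tibble(patient_id = id, onset_date = ORIGIN + relapses[[id]])
    }))
  }
  for (pc in c(
    "pos_pyramidal_tract", "pos_brainstem", "pos_bowel_bladder",
    "pos_cerebellum", "pos_visual_function", "pos_sensory"
  )) {
    rel[[pc]] <- rep(FALSE, nrow(rel))
  }
  crs <- if (is.null(courses)) {
    tibble::tibble(
      patient_id = ids, course = "RR", effective_date = ORIGIN - 3000
    )
  } else {
    courses
  }
  trt <- if (is.null(treatments)) {
    tibble::tibble(
      patient_id = character(), dmt_name = character(),
      start_date = as.Date(character()), end_date = as.Date(character())
    )
  } else {
    treatments
  }
  ms_cohort(pats, vis, rel, trt, crs,
    fampridine = fampridine, extraction_date = extraction_date
  )
}

# ---- independent brute-force labeler ---------------------------------------

bf_threshold <- function(b) {
  if (b == 0) 1.5 else if (b <= 5.5) 1.0 else 0.5
}

bf_w <- function(b, e2) as.integer(e2 - b >= bf_threshold(b))

# Straight-from-the-text episode labeler for one patient: loops over every
# EDSS visit, finds the last EDSS within (t0, t0+2y], confirms over
# (event, event+6m] plus the first EDSS after t0+2y, skipping measurements
# within one month after a relapse.
brute_force_episodes <- function(vdates, edss, relapse_dates, k = 3) {
  n <- length(vdates)
  out <- data.frame(
    t0 = as.Date(rep(NA, n)), w = NA_integer_, w_c = NA_integer_,
    validity = NA_character_
  )
  two_y <- 730.5
  six_m <- 182.625
  one_m <- 30.4375
  tainted <- function(d) {
    any(as.numeric(d) > as.numeric(relapse_dates) &
      as.numeric(d) <= as.numeric(relapse_dates) + one_m)
  }
  for (i in seq_len(n)) {
    t0 <- vdates[i]
    b <- edss[i]
    out$t0[i] <- t0
    in_out <- which(vdates > t0 & as.numeric(vdates - t0) <= two_y)
    w <- NA_integer_
    w_c <- NA_integer_
    validity <- "valid"
    if (length(in_out) == 0) {
      validity <- "invalid_no_outcome"
    } else {
      j <- in_out[length(in_out)]
      w <- bf_w(b, edss[j])
      if (w == 0) {
        w_c <- 0L
      } else {
        event <- vdates[j]
        conf <- c()
        for (q in seq_len(n)) {
          if (tainted(vdates[q])) next
          in6 <- vdates[q] > event & as.numeric(vdates[q] - event) <= six_m
          if (in6) conf <- union(conf, q)
        }
        aft <- which(as.numeric(vdates - t0) > two_y)
        aft <- aft[!vapply(vdates[aft], tainted, logical(1))]
        if (length(aft) > 0) conf <- union(conf, aft[1])
        if (length(conf) == 0) {
          validity <- "invalid_unconfirmable"
        } else {
          w_c <- as.integer(all(vapply(
            conf, function(q) bf_w(b, edss[q]), integer(1)
          ) == 1L))
        }
      }
    }
    n_hist <- sum(vdates <= t0 & as.numeric(t0 - vdates) <= 1186)
    if (n_hist < k) validity <- "invalid_insufficient_history"
    if (!t0 > as.Date("1990-01-01")) validity <- "invalid_pre1990"
    out$w[i] <- w
    out$w_c[i] <- w_c
    out$validity[i] <- validity
  }
  out
}

# Random small patient histories for labeling property tests.
random_patient_history <- function() {
  n <- sample(3:14, 1)
  days <- sort(sample(0:2500, n))
  edss <- sample(c(0, seq(1, 8, by = 0.5)), n, replace = TRUE)
  relapse_days <- if (runif(1) < 0.6) {
    sort(sample(0:2500, sample(1:4, 1)))
  } else {
    numeric(0)
  }
  list(days = days, edss = edss, relapse_days = relapse_days)
}

# ---- metric oracles --------------------------------------------------------

# O(n^2) pairwise concordance (ties count one half).
bf_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Small deterministic simulated scores/labels.
sim_scored_labels <- function(n, prevalence = 0.3, signal = 0, seed = 1) {
  set.seed(seed)
  s <- runif(n)
  p <- plogis(qlogis(prevalence) + signal * qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)))
  y <- rbinom(n, 1, p)
  list(scores = s, labels = y)
}

# Tiny simulated cohort shared by several expensive tests (memoised per
# test run).
tiny_cohort_env <- new.env()
tiny_cohort <- function() {
  if (is.null(tiny_cohort_env$coh)) {
    cfg <- sim_config(n_patients = 150, n_centers = 8, seed = 11)
    tiny_cohort_env$coh <- simulate_cohort(cfg)
    tiny_cohort_env$clean <- clean_cohort(tiny_cohort_env$coh)
    tiny_cohort_env$eps <- enumerate_episodes(tiny_cohort_env$clean, 3)
  }
  list(
    raw = tiny_cohort_env$coh, clean = tiny_cohort_env$clean,
    episodes = tiny_cohort_env$eps
  )
}
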
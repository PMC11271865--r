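#' Inverse-time transform for history features
#'
#' Elapsed times (years since the last relapse, disease duration until a
#' first DMT, ...) are mapped to `1/(1 + t)` so that recent events score
#' near 1 and the never-happened case has a well-defined value: an undefined
#' time returns 0, and a negative time (possible with inconsistent dates)
#' returns 1.
#'
#' @param t numeric vector of elapsed times in years; `NA` means the
#'   defining event never occurred.
#' @return values in `[0, 1]`.
#' @export
inverse_time_transform <- function(t) {
  ifelse(is.na(t), 0, ifelse(t < 0, 1, 1 / (1 + t)))
}

# Versioned feature layout: models refuse to score a matrix built under a
# different layout.
FEATURE_LAYOUT_VERSION <- "static-dynamic-v1"

EPISODE_KEYS <- c("patient_id", "center_id", "t0")

STATIC_COLS <- c(
  "sex_F", "sex_M", "age", "age_onset", "disease_duration",
  "course_RR", "course_SP", "course_PP", "edss_t0",
  "dmt_none", "dmt_low", "dmt_moderate", "dmt_high", "induction_active",
  paste0(KFS_COLS, "_t0"),
  "edu_higher", "edu_no_higher", "edu_unknown",
  "sym_supratentorial", "sym_optic_pathways", "sym_brainstem",
  "sym_spinal_cord", "sym_missing",
  "pred_time", "diag_time"
)

DYNAMIC_EXTRA_COLS <- c(
  "n_visits_3y", "edss_min", "edss_max", "edss_mean_3y", "edss_std_3y",
  "edss_oldest_3y",
  as.vector(t(outer(KFS_COLS, c("_min", "_max", "_mean_3y", "_std_3y", "_oldest_3y"), paste0))),
  paste0(KFS_COLS, "_unobserved"),
  "relapse_rate", "t_since_relapse_tr", "ever_high_dmt",
  "t_first_dmt_tr", "t_first_high_dmt_tr", "frac_dd_on_dmt",
  "t_fampridine_tr"
)

#' Static feature set for a table of episodes
#'
#' One row per episode with the variables available at the prediction time
#' without history aggregation: sex, age, age at onset, disease duration,
#' MS course, baseline EDSS, last DMT efficacy class at baseline (with
#' `none` when no DMT interval covers the baseline), an indicator for any
#' induction DMT started by baseline, the eight KFS scores at baseline
#' (0-filled when unrecorded), education and first-symptom indicators (with
#' explicit unknown/missing categories), and the prediction and diagnosis
#' times in years since 1990. Categorical variables are one-hot encoded;
#' after encoding no entry is missing.
#'
#' @param cohort an `ms_cohort`.
#' @param episodes episode tibble from [enumerate_episodes()] (any subset of
#'   its rows).
#' @return tibble: episode keys (`patient_id`, `center_id`, `t0`) followed by
#'   the static feature columns, in a versioned order.
#' @export
build_static_features <- function(cohort, episodes) {
  p <- cohort$patients[match(episodes$patient_id, cohort$patients$patient_id), ]
  t0 <- as.Date(episodes$t0)
  ref1990 <- as.Date("1990-01-01")

  course <- episodes$course_at_t0
  edu <- p$education
  sym <- p$first_symptom

  trt <- impute_treatment_ends(
    filter(cohort$treatments, .data$patient_id %in% unique(episodes$patient_id))
  )
  dmt_at <- dmt_class_at(trt, episodes$patient_id, t0)

  visits <- cohort$visits
  vkey <- paste(visits$patient_id, visits$visit_date)
  vi <- match(paste(episodes$patient_id, t0), vkey)
  kfs_t0 <- as.matrix(visits[vi, KFS_COLS])
  kfs_t0[is.na(kfs_t0)] <- 0

  out <- tibble(
    patient_id = episodes$patient_id,
    center_id = episodes$center_id,
    t0 = t0,
    sex_F = as.numeric(p$sex == "F"),
    sex_M = as.numeric(p$sex == "M"),
    age = years_between(p$birth_date, t0),
    age_onset = years_between(p$birth_date, p$ms_onset_date),
    disease_duration = years_between(p$ms_onset_date, t0),
    course_RR = as.numeric(course == "RR"),
    course_SP = as.numeric(course == "SP"),
    course_PP = as.numeric(course == "PP"),
    edss_t0 = episodes$baseline_edss,
    dmt_none = as.numeric(dmt_at == "none"),
    dmt_low = as.numeric(dmt_at == "low"),
    dmt_moderate = as.numeric(dmt_at == "moderate"),
    dmt_high = as.numeric(dmt_at == "high"),
    induction_active = induction_by(trt, episodes$patient_id, t0)
  )
  for (j in seq_along(KFS_COLS)) {
    out[[paste0(KFS_COLS[j], "_t0")]] <- unname(kfs_t0[, j])
  }
  out <- out |>
    mutate(
      edu_higher = as.numeric(!is.na(edu) & edu == "higher"),
      edu_no_higher = as.numeric(!is.na(edu) & edu == "no_higher"),
      edu_unknown = as.numeric(is.na(edu)),
      sym_supratentorial = as.numeric(!is.na(sym) & sym == "supratentorial"),
      sym_optic_pathways = as.numeric(!is.na(sym) & sym == "optic_pathways"),
      sym_brainstem = as.numeric(!is.na(sym) & sym == "brainstem"),
      sym_spinal_cord = as.numeric(!is.na(sym) & sym == "spinal_cord"),
      sym_missing = as.numeric(is.na(sym)),
      pred_time = years_between(ref1990, t0),
      diag_time = years_between(ref1990, p$diagnosis_date)
    )
  stopifnot(identical(names(out), c(EPISODE_KEYS, STATIC_COLS)))
  out
}

# Efficacy class of the (non-induction) treatment interval covering each t0;
# "none" when no interval covers it. Open intervals cover everything after
# their start.
dmt_class_at <- function(trt, patient_ids, t0) {
  res <- rep("none", length(patient_ids))
  if (nrow(trt) == 0) {
    return(res)
  }
  trt <- filter(trt, .data$efficacy_class != "high_induction")
  sp <- split(seq_len(nrow(trt)), trt$patient_id)
  for (pid in unique(patient_ids)) {
    rows <- sp[[pid]]
    if (is.null(rows)) next
    eps <- which(patient_ids == pid)
    for (r in rows) {
      covered <- t0[eps] >= trt$start_date[r] &
        (is.na(trt$end_date[r]) | t0[eps] <= trt$end_date[r])
      res[eps[covered]] <- trt$efficacy_class[r]
    }
  }
  res
}

induction_by <- function(trt, patient_ids, t0) {
  ind <- filter(trt, .data$efficacy_class == "high_induction")
  if (nrow(ind) == 0) {
    return(rep(0, length(patient_ids)))
  }
  sp <- split(as.numeric(ind$start_date), ind$patient_id)
  map_dbl(seq_along(patient_ids), function(i) {
    s <- sp[[patient_ids[i]]]
    as.numeric(!is.null(s) && any(s <= as.numeric(t0[i])))
  })
}

#' Dynamic feature set (history summaries) for a table of episodes
#'
#' Extends [build_static_features()] with hand-engineered summaries of the
#' clinical history up to the baseline: visit count over the trailing 3.25
#' years (1186 days); whole-history minimum and maximum, trailing-window
#' mean, population standard deviation and oldest value of the EDSS and of
#' each KFS score (statistics over observed values only, with a companion
#' indicator when a KFS was never observed); whole-history annualized
#' relapse rate (count divided by years since the first clinical visit);
#' `1/(1+t)`-transformed times since the last relapse and last Fampridine
#' administration; an ever-on-high-efficacy-DMT indicator; transformed
#' disease durations until the first DMT and first high-efficacy DMT; and
#' the fraction of disease duration spent on a DMT.
#'
#' @inheritParams build_static_features
#' @return tibble: episode keys, static columns, then dynamic columns, in a
#'   versioned order.
#' @export
build_dynamic_features <- function(cohort, episodes) {
  st <- build_static_features(cohort, episodes)
  p <- cohort$patients[match(episodes$patient_id, cohort$patients$patient_id), ]
  t0 <- as.Date(episodes$t0)

  visits <- cohort$visits |>
    filter(!is.na(.data$edss)) |>
    arrange(.data$patient_id, .data$visit_date)
  vsplit <- split(seq_len(nrow(visits)), visits$patient_id)
  rsplit <- split(as.numeric(as.Date(cohort$relapses$onset_date)), cohort$relapses$patient_id)
  fsplit <- split(as.numeric(as.Date(cohort$fampridine$date)), cohort$fampridine$patient_id)
  trt <- impute_treatment_ends(
    filter(cohort$treatments, .data$patient_id %in% unique(episodes$patient_id))
  )
  tsplit <- split(seq_len(nrow(trt)), trt$patient_id)

  n_ep <- nrow(episodes)
  dyn <- matrix(0, n_ep, length(DYNAMIC_EXTRA_COLS),
    dimnames = list(NULL, DYNAMIC_EXTRA_COLS)
  )
  zero_follow_up <- FALSE

  for (pid in unique(episodes$patient_id)) {
    eps <- which(episodes$patient_id == pid)
    rows <- vsplit[[pid]]
    vd <- as.numeric(as.Date(visits$visit_date[rows]))
    ve <- visits$edss[rows]
    vkfs <- as.matrix(visits[rows, KFS_COLS])
    # episode baselines are EDSS-bearing visits, so each t0 is in vd
    i_t0 <- match(as.numeric(t0[eps]), vd)
    lo <- findInterval(vd[i_t0] - DAYS_3Y3M - 1e-9, vd) + 1L

    dyn[eps, "n_visits_3y"] <- i_t0 - lo + 1L
    dyn[eps, "edss_min"] <- cummin(ve)[i_t0]
    dyn[eps, "edss_max"] <- cummax(ve)[i_t0]
    cs <- cumsum(ve)
    cs2 <- cumsum(ve^2)
    wsum <- cs[i_t0] - ifelse(lo > 1, cs[lo - 1], 0)
    wsum2 <- cs2[i_t0] - ifelse(lo > 1, cs2[lo - 1], 0)
    wn <- i_t0 - lo + 1L
    mu <- wsum / wn
    dyn[eps, "edss_mean_3y"] <- mu
    dyn[eps, "edss_std_3y"] <- sqrt(pmax(wsum2 / wn - mu^2, 0))
    dyn[eps, "edss_oldest_3y"] <- ve[lo]

    for (j in seq_along(KFS_COLS)) {
      k <- KFS_COLS[j]
      x <- vkfs[, j]
      obs <- !is.na(x)
      x0 <- ifelse(obs, x, 0)
      c_obs <- cumsum(obs)
      c_s <- cumsum(x0)
      c_s2 <- cumsum(x0^2)
      cmin <- cummin(ifelse(obs, x, Inf))
      cmax <- cummax(ifelse(obs, x, -Inf))
      n_hist_obs <- c_obs[i_t0]
      dyn[eps, paste0(k, "_unobserved")] <- as.numeric(n_hist_obs == 0)
      dyn[eps, paste0(k, "_min")] <- ifelse(n_hist_obs > 0, cmin[i_t0], 0)
      dyn[eps, paste0(k, "_max")] <- ifelse(n_hist_obs > 0, cmax[i_t0], 0)
      wobs <- c_obs[i_t0] - ifelse(lo > 1, c_obs[lo - 1], 0)
      ws <- c_s[i_t0] - ifelse(lo > 1, c_s[lo - 1], 0)
      ws2 <- c_s2[i_t0] - ifelse(lo > 1, c_s2[lo - 1], 0)
      muk <- ifelse(wobs > 0, ws / wobs, 0)
      dyn[eps, paste0(k, "_mean_3y")] <- muk
      dyn[eps, paste0(k, "_std_3y")] <- ifelse(
        wobs > 0, sqrt(pmax(ws2 / wobs - muk^2, 0)), 0
      )
      # oldest observed value inside the trailing window
      obs_idx <- which(obs)
      first_obs <- obs_idx[findInterval(lo - 1L, obs_idx) + 1L]
      dyn[eps, paste0(k, "_oldest_3y")] <- ifelse(
        !is.na(first_obs) & first_obs <= i_t0, x[first_obs], 0
      )
    }

    rel <- sort(rsplit[[pid]] %||% numeric(0))
    n_rel <- findInterval(vd[i_t0], rel)
    fy <- (vd[i_t0] - vd[1]) / DAYS_PER_YEAR
    if (any(fy <= 0 & n_rel > 0)) zero_follow_up <- TRUE
    dyn[eps, "relapse_rate"] <- ifelse(fy > 0, n_rel / fy, 0)
    last_rel <- ifelse(n_rel > 0, rel[pmax(n_rel, 1)], NA)
    dyn[eps, "t_since_relapse_tr"] <- inverse_time_transform(
      (vd[i_t0] - last_rel) / DAYS_PER_YEAR
    )

    fam <- sort(fsplit[[pid]] %||% numeric(0))
    n_fam <- findInterval(vd[i_t0], fam)
    last_fam <- ifelse(n_fam > 0, fam[pmax(n_fam, 1)], NA)
    dyn[eps, "t_fampridine_tr"] <- inverse_time_transform(
      (vd[i_t0] - last_fam) / DAYS_PER_YEAR
    )

    onset <- as.numeric(p$ms_onset_date[match(pid, p$patient_id)])
    trows <- tsplit[[pid]]
    if (!is.null(trows)) {
      starts <- as.numeric(trt$start_date[trows])
      ends <- as.numeric(trt$end_date[trows])
      cls <- trt$efficacy_class[trows]
      high <- cls %in% c("high", "high_induction")
      for (e in eps) {
        tn <- as.numeric(t0[e])
        started <- starts <= tn
        dyn[e, "ever_high_dmt"] <- as.numeric(any(started & high))
        first_dmt <- if (any(started)) min(starts[started]) else NA
        dyn[e, "t_first_dmt_tr"] <- inverse_time_transform(
          (first_dmt - onset) / DAYS_PER_YEAR
        )
        first_high <- if (any(started & high)) min(starts[started & high]) else NA
        dyn[e, "t_first_high_dmt_tr"] <- inverse_time_transform(
          (first_high - onset) / DAYS_PER_YEAR
        )
        # union of non-induction intervals clipped to [onset, t0]
        ni <- cls != "high_induction" & started
        if (any(ni) && tn > onset) {
          a <- pmax(starts[ni], onset)
          b <- pmin(ifelse(is.na(ends[ni]), tn, ends[ni]), tn)
          ord <- order(a)
          a <- a[ord]
          b <- b[ord]
          tot <- 0
          cur_a <- a[1]
          cur_b <- b[1]
          for (q in seq_along(a)[-1]) {
            if (a[q] > cur_b) {
              tot <- tot + max(cur_b - cur_a, 0)
              cur_a <- a[q]
              cur_b <- b[q]
            } else {
              cur_b <- max(cur_b, b[q])
            }
          }
          tot <- tot + max(cur_b - cur_a, 0)
          dyn[e, "frac_dd_on_dmt"] <- min(tot / (tn - onset), 1)
        }
      }
    } else {
      dyn[eps, "t_first_dmt_tr"] <- 0
      dyn[eps, "t_first_high_dmt_tr"] <- 0
    }
  }
  if (zero_follow_up) {
    warn("episodes with zero follow-up duration: relapse rate set to 0")
  }

  out <- bind_cols(st, as_tibble(dyn))
  attr(out, "layout") <- FEATURE_LAYOUT_VERSION
  out
}

#' Longitudinal event sequences for a table of episodes
#'
#' For each episode, builds the timestamped sequence of clinical events in
#' the observation window (all history up to the baseline): one step per
#' distinct event date (visit, relapse, treatment start/end, Fampridine
#' administration), with channels for EDSS, the eight KFS scores, relapse
#' occurrence and position (brainstem / pyramidal tract / other), cumulative
#' relapse count, course indicators, active DMT efficacy class, induction
#' DMT start, and Fampridine administration, plus one observation mask per
#' measured channel. Channels observed on the same date share a single step.
#' Times are years before baseline (non-positive, increasing towards 0).
#'
#' The repetition of the static and dynamic feature vector along the
#' sequence (used by the attention model) is done at model-input assembly,
#' not here.
#'
#' @inheritParams build_static_features
#' @return tibble with episode keys and a `seq` list-column of numeric
#'   matrices (rows = steps; columns `time`, channels, then `mask_*`
#'   columns).
#' @export
build_longitudinal_sequences <- function(cohort, episodes) {
  visits <- cohort$visits |> arrange(.data$patient_id, .data$visit_date)
  vsplit <- split(visits, visits$patient_id)
  rsplit <- split(cohort$relapses, cohort$relapses$patient_id)
  fsplit <- split(cohort$fampridine, cohort$fampridine$patient_id)
  csplit <- split(cohort$courses, cohort$courses$patient_id)
  trt <- impute_treatment_ends(
    filter(cohort$treatments, .data$patient_id %in% unique(episodes$patient_id))
  )
  tsplit <- split(trt, trt$patient_id)

  seqs <- map(seq_len(nrow(episodes)), function(i) {
    episode_sequence(
      episodes$patient_id[i], as.Date(episodes$t0[i]),
      vsplit, rsplit, fsplit, csplit, tsplit
    )
  })
  tibble(
    patient_id = episodes$patient_id,
    center_id = episodes$center_id,
    t0 = as.Date(episodes$t0),
    seq = seqs
  )
}

SEQ_MEASURED <- c("edss", KFS_COLS)
SEQ_CHANNELS <- c(
  SEQ_MEASURED,
  "relapse_occ", "relapse_brainstem", "relapse_pyramidal", "relapse_other",
  "cum_relapse", "course_RR", "course_SP", "course_PP",
  "dmt_none", "dmt_low", "dmt_moderate", "dmt_high",
  "induction_start", "fampridine"
)

episode_sequence <- function(pid, t0, vsplit, rsplit, fsplit, csplit, tsplit) {
  v <- vsplit[[pid]]
  v <- v[as.Date(v$visit_date) <= t0, , drop = FALSE]
  r <- rsplit[[pid]]
  r <- if (is.null(r)) NULL else r[as.Date(r$onset_date) <= t0, , drop = FALSE]
  f <- fsplit[[pid]]
  f <- if (is.null(f)) NULL else f[as.Date(f$date) <= t0, , drop = FALSE]
  trt <- tsplit[[pid]]
  trt <- if (is.null(trt)) NULL else trt[as.Date(trt$start_date) <= t0, , drop = FALSE]
  crs <- csplit[[pid]]

  dates <- sort(unique(c(
    as.Date(v$visit_date),
    if (!is.null(r)) as.Date(r$onset_date),
    if (!is.null(f)) as.Date(f$date),
    if (!is.null(trt)) as.Date(trt$start_date),
    if (!is.null(trt)) as.Date(trt$end_date[!is.na(trt$end_date) & trt$end_date <= t0])
  )))
  n <- length(dates)
  m <- matrix(0, n, 1 + length(SEQ_CHANNELS) + length(SEQ_MEASURED),
    dimnames = list(NULL, c(
      "time", SEQ_CHANNELS, paste0("mask_", SEQ_MEASURED)
    ))
  )
  m[, "time"] <- as.numeric(dates - t0) / DAYS_PER_YEAR

  vi <- match(as.Date(v$visit_date), dates)
  m[vi, "edss"] <- replace_na(v$edss, 0)
  m[vi, "mask_edss"] <- as.numeric(!is.na(v$edss))
  for (k in KFS_COLS) {
    m[vi, k] <- replace_na(v[[k]], 0)
    m[vi, paste0("mask_", k)] <- as.numeric(!is.na(v[[k]]))
  }
  if (!is.null(r) && nrow(r) > 0) {
    ri <- match(as.Date(r$onset_date), dates)
    m[ri, "relapse_occ"] <- 1
    m[ri, "relapse_brainstem"] <- as.numeric(r$pos_brainstem)
    m[ri, "relapse_pyramidal"] <- as.numeric(r$pos_pyramidal_tract)
    m[ri, "relapse_other"] <- as.numeric(
      r$pos_bowel_bladder | r$pos_cerebellum | r$pos_visual_function | r$pos_sensory
    )
    cum <- rep(0, n)
    cum[ri] <- 1
    m[, "cum_relapse"] <- cumsum(cum)
  }
  course_v <- if (is.null(crs)) rep(NA_character_, n) else course_at(crs, dates)
  m[, "course_RR"] <- as.numeric(!is.na(course_v) & course_v == "RR")
  m[, "course_SP"] <- as.numeric(!is.na(course_v) & course_v == "SP")
  m[, "course_PP"] <- as.numeric(!is.na(course_v) & course_v == "PP")
  if (!is.null(trt) && nrow(trt) > 0) {
    cls_at <- dmt_class_at(trt, rep(pid, n), dates)
    m[, "dmt_low"] <- as.numeric(cls_at == "low")
    m[, "dmt_moderate"] <- as.numeric(cls_at == "moderate")
    m[, "dmt_high"] <- as.numeric(cls_at == "high")
    ind <- trt[trt$efficacy_class == "high_induction", , drop = FALSE]
    if (nrow(ind) > 0) {
      m[match(as.Date(ind$start_date), dates), "induction_start"] <- 1
    }
  }
  m[, "dmt_none"] <- as.numeric(
    m[, "dmt_low"] + m[, "dmt_moderate"] + m[, "dmt_high"] == 0
  )
  if (!is.null(f) && nrow(f) > 0) {
    m[match(as.Date(f$date), dates), "fampridine"] <- 1
  }
  m
}

#' Numeric feature matrix from a feature tibble
#'
#' Drops the episode key columns and returns the numeric matrix models
#' consume, carrying the feature-layout version as an attribute.
#'
#' @param features output of [build_static_features()] or
#'   [build_dynamic_features()].
#' @return numeric matrix with named columns.
#' @export
feature_matrix <- function(features) {
  x <- as.matrix(features[setdiff(names(features), EPISODE_KEYS)])
  attr(x, "layout") <- attr(features, "layout") %||% FEATURE_LAYOUT_VERSION
  x
}
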
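#' EDSS worsening threshold for a given baseline
#'
#' Because the EDSS is non-linear, the minimal increase that counts as
#' disability progression depends on the baseline score: 1.5 points from a
#' baseline of 0, 1.0 point for baselines in (0, 5.5], and 0.5 points above
#' 5.5.
#'
#' @param baseline_edss numeric vector of baseline EDSS values.
#' @return numeric vector of minimal worsening increments.
#' @export
progression_threshold <- function(baseline_edss) {
  ifelse(baseline_edss == 0, 1.5, ifelse(baseline_edss <= 5.5, 1.0, 0.5))
}

#' Unconfirmed disability progression rule
#'
#' Compares a follow-up EDSS against a baseline EDSS and returns 1 when the
#' increase reaches the baseline-dependent worsening threshold (see
#' [progression_threshold()]), else 0.
#'
#' @param edss_t0 baseline EDSS (valid grid values, see [is_edss()]).
#' @param edss_t2y follow-up EDSS, typically the last value recorded within
#'   the two-year horizon.
#' @return integer vector of 0/1 labels.
#' @export
unconfirmed_progression <- function(edss_t0, edss_t2y) {
  if (any(!is_edss(edss_t0)) || any(!is_edss(edss_t2y))) {
    abort("EDSS values must lie on the half-point grid (0, 1.0, 1.5, ..., 10.0)",
      class = "msprog_domain_error"
    )
  }
  as.integer(edss_t2y - edss_t0 >= progression_threshold(edss_t0))
}

#' Outcome EDSS at the two-year horizon
#'
#' Returns the last EDSS-bearing visit strictly after the baseline and at most
#' two years (730.5 days) later — the measurement against which progression is
#' assessed.
#'
#' @param visits tibble with `visit_date` and `edss` for one patient.
#' @param t0 baseline date.
#' @return a one-row tibble with `edss_t2y` and `measurement_date`, or `NULL`
#'   when no EDSS is recorded in the outcome window.
#' @export
outcome_edss <- function(visits, t0) {
  d <- as.Date(visits$visit_date)
  keep <- !is.na(visits$edss) & d > t0 & as.numeric(d - t0) <= DAYS_2Y
  if (!any(keep)) {
    return(NULL)
  }
  i <- which(keep)[which.max(d[keep])]
  tibble(edss_t2y = visits$edss[i], measurement_date = d[i])
}

# Dates within one month after a relapse onset are unreliable EDSS readings
# (transient relapse-related worsening) and are excluded from confirmation.
post_relapse_tainted <- function(dates, relapse_onsets) {
  if (length(relapse_onsets) == 0) {
    return(rep(FALSE, length(dates)))
  }
  vapply(as.numeric(dates), function(d) {
    any(d > as.numeric(relapse_onsets) &
      d <= as.numeric(relapse_onsets) + DAYS_1M)
  }, logical(1))
}

#' Confirm a progression event over six months
#'
#' Given an episode with an unconfirmed label, builds the confirmation set —
#' all EDSS-bearing visits within six months after the progression event plus
#' the first EDSS measurement after the two-year horizon, excluding any
#' measurement within one month after a relapse onset — and re-applies the
#' worsening rule to each member.
#'
#' @param episode a list or one-row data frame with `t0`, `baseline_edss`,
#'   `w`, and (when `w == 1`) `event_date`, the date of the outcome EDSS
#'   measurement.
#' @param visits tibble of the patient's visits (`visit_date`, `edss`).
#' @param relapses tibble of the patient's relapses (`onset_date`), or `NULL`.
#' @return list with `w_c` (0, 1, or `NA`) and `validity` (`"valid"` or
#'   `"invalid_unconfirmable"`).
#' @export
confirm_progression <- function(episode, visits, relapses = NULL) {
  w <- episode$w
  if (is.na(w)) {
    return(list(w_c = NA_integer_, validity = "invalid_no_outcome"))
  }
  if (w == 0) {
    return(list(w_c = 0L, validity = "valid"))
  }
  t0 <- as.Date(episode$t0)
  event <- as.Date(episode$event_date)
  d <- as.Date(visits$visit_date)
  has_edss <- !is.na(visits$edss)
  onsets <- if (is.null(relapses) || nrow(relapses) == 0) {
    as.Date(character())
  } else {
    as.Date(relapses$onset_date)
  }
  eligible <- has_edss & !post_relapse_tainted(d, onsets)

  in_6m <- eligible & d > event & as.numeric(d - event) <= DAYS_6M
  after_2y <- eligible & as.numeric(d - t0) > DAYS_2Y
  first_after <- if (any(after_2y)) which(after_2y)[which.min(d[after_2y])] else integer(0)
  conf_idx <- union(which(in_6m), first_after)
  if (length(conf_idx) == 0) {
    return(list(w_c = NA_integer_, validity = "invalid_unconfirmable"))
  }
  re_w <- unconfirmed_progression(
    rep(episode$baseline_edss, length(conf_idx)), visits$edss[conf_idx]
  )
  list(w_c = as.integer(all(re_w == 1L)), validity = "valid")
}

#' Validity of a candidate episode
#'
#' An episode is valid when a confirmed label could be computed, the baseline
#' date falls after 1990-01-01 (strictly), and at least `k` EDSS-bearing
#' visits fall within the preceding 3.25 years (1186 days, baseline
#' included). When several rules fail, the first failing rule in the order
#' pre-1990, insufficient history, missing outcome, unconfirmable is
#' reported.
#'
#' @param episode list or one-row data frame with `t0`, `w`, `w_c`, and
#'   optionally `conf_validity` (from [confirm_progression()]).
#' @param visits the patient's visits.
#' @param k minimal number of EDSS measurements in the trailing window
#'   (3 by default, 6 for the stricter cohort).
#' @return a validity string.
#' @export
episode_validity <- function(episode, visits, k = 3) {
  t0 <- as.Date(episode$t0)
  if (!(t0 > as.Date("1990-01-01"))) {
    return("invalid_pre1990")
  }
  d <- as.Date(visits$visit_date)
  n_hist <- sum(!is.na(visits$edss) & d <= t0 & as.numeric(t0 - d) <= DAYS_3Y3M)
  if (n_hist < k) {
    return("invalid_insufficient_history")
  }
  if (is.na(episode$w)) {
    return("invalid_no_outcome")
  }
  if (is.na(episode$w_c)) {
    return("invalid_unconfirmable")
  }
  "valid"
}

# Course in effect at a date: most recent course record with effective_date
# <= t0; before the first record, the first record's course is assumed to
# apply retrospectively.
course_at <- function(courses, t0) {
  if (nrow(courses) == 0) {
    return(NA_character_)
  }
  eff <- as.Date(courses$effective_date)
  ord <- order(eff)
  eff <- eff[ord]
  crs <- courses$course[ord]
  i <- findInterval(as.numeric(t0), as.numeric(eff))
  ifelse(i == 0, crs[1], crs[pmax(i, 1)])
}

#' Enumerate and label all candidate clinical episodes
#'
#' Every EDSS-bearing visit of every patient is a candidate baseline for a
#' two-year progression episode. Each candidate is labeled with the
#' unconfirmed rule, passed through six-month confirmation with relapse
#' exclusion, and tagged with a validity status. Overlapping episodes of one
#' patient are deliberately kept: they augment the data set.
#'
#' @param cohort a (preferably cleaned) `ms_cohort`.
#' @param k minimal number of EDSS measurements in the trailing 3.25 years
#'   (3 or 6).
#' @return tibble with one row per candidate episode: `patient_id`,
#'   `center_id`, `t0`, `baseline_edss`, `course_at_t0`, `event_date`,
#'   `edss_t2y`, `w`, `w_c`, `validity`, `valid`. The per-rule exclusion
#'   tally is attached as attribute `"exclusions"` (see
#'   [episode_exclusions()]).
#' @export
enumerate_episodes <- function(cohort, k = 3) {
  validate_cohort(cohort)
  stopifnot(k >= 1)
  centers <- setNames(cohort$patients$center_id, cohort$patients$patient_id)

  visits <- cohort$visits |>
    filter(!is.na(.data$edss), !is.na(.data$visit_date)) |>
    arrange(.data$patient_id, .data$visit_date)
  relapse_split <- split(as.Date(cohort$relapses$onset_date), cohort$relapses$patient_id)
  course_split <- split(cohort$courses, cohort$courses$patient_id)

  per_patient <- function(df) {
    pid <- df$patient_id[1]
    d <- as.Date(df$visit_date)
    dn <- as.numeric(d)
    edss <- df$edss
    n <- length(dn)
    onsets <- relapse_split[[pid]] %||% as.Date(character())
    tainted <- post_relapse_tainted(d, onsets)

    # outcome: last visit with date in (t0, t0 + 2y]
    hi <- findInterval(dn + DAYS_2Y, dn)
    out_idx <- ifelse(hi > seq_len(n), hi, NA_integer_)
    # history count: visits in [t0 - 3.25y, t0]
    lo <- findInterval(dn - DAYS_3Y3M - 1e-9, dn)
    n_hist <- seq_len(n) - lo

    w <- rep(NA_integer_, n)
    has_out <- !is.na(out_idx)
    if (any(has_out)) {
      w[has_out] <- unconfirmed_progression(edss[has_out], edss[out_idx[has_out]])
    }

    w_c <- rep(NA_integer_, n)
    w_c[which(w == 0L)] <- 0L
    for (i in which(w == 1L)) {
      event <- dn[out_idx[i]]
      in_6m <- !tainted & dn > event & (dn - event) <= DAYS_6M
      after_2y <- !tainted & (dn - dn[i]) > DAYS_2Y
      conf_idx <- which(in_6m)
      if (any(after_2y)) conf_idx <- union(conf_idx, which(after_2y)[1])
      if (length(conf_idx) > 0) {
        w_c[i] <- as.integer(all(
          unconfirmed_progression(rep(edss[i], length(conf_idx)), edss[conf_idx]) == 1L
        ))
      }
    }

    validity <- rep("valid", n)
    validity[is.na(w_c)] <- "invalid_unconfirmable"
    validity[is.na(w)] <- "invalid_no_outcome"
    validity[n_hist < k] <- "invalid_insufficient_history"
    validity[dn <= as.numeric(as.Date("1990-01-01"))] <- "invalid_pre1990"

    tibble(
      patient_id = pid,
      t0 = d,
      baseline_edss = edss,
      course_at_t0 = course_at(course_split[[pid]] %||% tibble(course = character(), effective_date = as.Date(character())), d),
      event_date = as.Date(ifelse(has_out, dn[pmax(out_idx, 1)], NA), origin = "1970-01-01"),
      edss_t2y = ifelse(has_out, edss[pmax(out_idx, 1)], NA_real_),
      w = w, w_c = w_c, validity = validity
    )
  }

  episodes <- visits |>
    group_split(.data$patient_id) |>
    map(per_patient) |>
    list_rbind()

  if (nrow(episodes) == 0) {
    episodes <- tibble(
      patient_id = character(), t0 = as.Date(character()),
      baseline_edss = numeric(), course_at_t0 = character(),
      event_date = as.Date(character()), edss_t2y = numeric(),
      w = integer(), w_c = integer(), validity = character()
    )
  }
  episodes <- episodes |>
    mutate(
      center_id = unname(centers[.data$patient_id]),
      valid = .data$validity == "valid",
      .after = "patient_id"
    )
  tally <- episodes |> count(.data$validity, name = "n")
  attr(episodes, "exclusions") <- tally
  attr(episodes, "k") <- k
  episodes
}

#' Exclusion tally of an episode table
#'
#' @param episodes result of [enumerate_episodes()].
#' @return tibble of counts per validity category.
#' @export
episode_exclusions <- function(episodes) {
  attr(episodes, "exclusions") %||% count(episodes, .data$validity, name = "n")
}

#' Clean a raw registry cohort
#'
#' Applies the data-quality exclusion rules, in order: visits with invalid
#' dates or after the extraction date are dropped; visits before 1970 are
#' dropped; same-day visits of one patient with conflicting EDSS values are
#' all removed while exact same-day duplicates are reduced to one; patients
#' whose last course record is CIS are removed; patients with missing
#' diagnosis or onset dates, missing course or sex, or key dates after the
#' extraction date are removed.
#'
#' @param raw an `ms_cohort`.
#' @return a cleaned `ms_cohort`; the per-rule exclusion tally is in
#'   `attr(, "exclusions")`. The operation is idempotent.
#' @export
clean_cohort <- function(raw) {
  validate_cohort(raw)
  extraction <- attr(raw, "extraction_date")
  tally <- list()

  v <- raw$visits
  bad_date <- is.na(v$visit_date) | v$visit_date > extraction
  tally$visit_invalid_date <- sum(bad_date)
  v <- v[!bad_date, , drop = FALSE]

  pre1970 <- v$visit_date < as.Date("1970-01-01")
  tally$visit_pre1970 <- sum(pre1970)
  v <- v[!pre1970, , drop = FALSE]

  v <- v |>
    group_by(.data$patient_id, .data$visit_date) |>
    mutate(
      .n_edss = dplyr::n_distinct(.data$edss[!is.na(.data$edss)]),
      .dup = dplyr::row_number()
    ) |>
    ungroup()
  conflict <- v$.n_edss >= 2
  tally$visit_same_day_conflict <- sum(conflict)
  dup <- !conflict & v$.dup > 1
  tally$visit_same_day_duplicate <- sum(dup)
  v <- v[!conflict & !dup, !(names(v) %in% c(".n_edss", ".dup"))]

  p <- raw$patients
  last_course <- raw$courses |>
    filter(!is.na(.data$effective_date)) |>
    group_by(.data$patient_id) |>
    slice_max(.data$effective_date, n = 1, with_ties = FALSE) |>
    ungroup()
  cis_ids <- last_course$patient_id[last_course$course == "CIS"]
  drop_cis <- p$patient_id %in% cis_ids
  tally$patient_cis_at_last_visit <- sum(drop_cis)
  p <- p[!drop_cis, , drop = FALSE]

  bad_dates <- is.na(p$diagnosis_date) | is.na(p$ms_onset_date)
  tally$patient_missing_key_date <- sum(bad_dates)
  p <- p[!bad_dates, , drop = FALSE]

  has_course <- p$patient_id %in% raw$courses$patient_id
  no_course_or_sex <- !has_course | is.na(p$sex)
  tally$patient_missing_course_or_sex <- sum(no_course_or_sex)
  p <- p[!no_course_or_sex, , drop = FALSE]

  future_dates <- p$birth_date > extraction |
    p$ms_onset_date > extraction |
    p$diagnosis_date > extraction
  future_dates[is.na(future_dates)] <- TRUE
  tally$patient_date_after_extraction <- sum(future_dates)
  p <- p[!future_dates, , drop = FALSE]

  keep <- p$patient_id
  out <- ms_cohort(
    patients = p,
    visits = filter(v, .data$patient_id %in% keep),
    relapses = filter(raw$relapses, .data$patient_id %in% keep, !is.na(.data$onset_date)),
    treatments = filter(raw$treatments, .data$patient_id %in% keep, !is.na(.data$start_date)),
    courses = filter(raw$courses, .data$patient_id %in% keep),
    fampridine = filter(raw$fampridine, .data$patient_id %in% keep),
    extraction_date = extraction,
    latent = attr(raw, "latent")
  )
  attr(out, "exclusions") <- tibble(
    rule = names(tally), n = unlist(tally, use.names = FALSE)
  )
  out
}
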
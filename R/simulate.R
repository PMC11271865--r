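DMT_VOCAB <- list(
  low = c("Interferons", "Teriflunomide", "Glatiramer", "Azathioprine", "Methotrexate"),
  moderate = c("Fingolimod", "Dimethyl-Fumarate", "Cladribine", "Siponimod", "Daclizumab"),
  high = c("Alemtuzumab", "Rituximab", "Ocrelizumab", "Natalizumab"),
  high_induction = c("Mitoxantrone", "Cyclophosphamide")
)

#' Configuration for the synthetic registry generator
#'
#' Returns the default simulation configuration, optionally overridden. The
#' defaults emulate the marginal structure of a large multi-center MS
#' registry: mean age at last visit about 42.8 years, onset age about 31.3
#' years, a course mix of roughly 83.5% relapsing-remitting (RR), 5% primary
#' progressive (PP) and 11.5% secondary progressive (SP) at the last visit,
#' irregular visits at about 1.5 per year, and an episode-level confirmed
#' progression prevalence near 11.64%.
#'
#' The ground-truth risk law: sustained disability steps arrive per patient
#' as an inhomogeneous Poisson process whose risk over the nominal outcome
#' horizon is logistic in the current history summaries,
#' `plogis(qlogis(base_rate) + sum(beta * (x(t) - center)))`, with `x(t)`
#' the EDSS at the last visit (saturating at 7.5), the whole-history
#' annualized relapse rate, and the SP/PP course indicators, held constant
#' between visits. With all coefficients zero every episode's risk equals
#' `base_rate`. Because the risk depends only on quantities that the
#' feature-engineering module reconstructs from the tables, the Bayes
#' discrimination level is attainable by models trained on those features.
#'
#' @param n_patients number of patients.
#' @param n_centers number of clinical centers; sizes are drawn heavy-tailed
#'   (log-normal weights) so small-center behavior is exercisable.
#' @param seed integer seed; identical config and seed give byte-identical
#'   cohort tables.
#' @param ... overrides for any default element (see the function body for
#'   the full list: demographics, follow-up, visit and relapse processes,
#'   EDSS walk, DMT policy, missingness, risk law).
#' @return a `ms_sim_config` list.
#' @export
sim_config <- function(n_patients = 1000, n_centers = 15, seed = 1, ...) {
  cfg <- list(
    n_patients = n_patients,
    n_centers = n_centers,
    seed = seed,
    extraction_date = as.Date("2020-09-01"),
    # demographics (targets the registry's Table-1-style marginals)
    sex_female = 0.718,
    onset_age = list(mean = 31.3, sd = 8.9, min = 10, max = 60),
    disease_duration = list(mean = 11.6, sd = 8.0, min = 2, max = 45),
    education = list(p_missing = 0.651, p_higher_observed = 0.182),
    first_symptom = list(
      p_missing = 0.137,
      probs = c(
        supratentorial = 0.282, optic_pathways = 0.226,
        brainstem = 0.243, spinal_cord = 0.264
      )
    ),
    # course mix at the last visit; SP patients start RR and convert
    course_mix = c(RR = 0.835, PP = 0.05, SP = 0.115),
    cis_rate = 0.02, # extra share of CIS-at-last patients (removed by cleaning)
    # visit process
    visit_rate = 1.5, # mean visits / year
    min_gap_days = 21,
    # relapse process
    relapse = list(
      rate_rr = 0.95, # per year at onset, RR phase
      decay = 0.04, # exponential decay per disease-year
      rate_progressive = 0.15,
      bump_range = c(0.5, 2.0), # transient EDSS bump, grid points
      bump_decay_days = 91
    ),
    # EDSS random walk (latent level; snapped to the half-point grid)
    edss_walk = list(
      start = list(RR = c(mean = 1.6, sd = 1.0), PP = c(mean = 3.2, sd = 1.2)),
      drift = c(RR = 0.02, SP = 0.06, PP = 0.07), # points / year
      volatility = 0.22 # sd of latent step per sqrt(year)
    ),
    # ground-truth progression risk law
    risk = list(
      base_rate = 0.1164, # episode risk at the centering point
      horizon_years = 1.33, # nominal outcome span (typical time from the
      # baseline to the last EDSS measurement inside the two-year window)
      beta = c(edss = 0.30, relapse_rate = 0.40, sp = 0.45, pp = 0.45),
      # centering near the visit-level population means keeps base_rate
      # interpretable as the typical episode risk
      center = c(edss = 3.5, relapse_rate = 1.1),
      step_margin = 0.5 # extra grid steps beyond the worsening threshold
    ),
    # treatments
    dmt = list(
      p_never = 0.235,
      class_probs = c(low = 0.55, moderate = 0.20, high = 0.15, high_induction = 0.10),
      mean_duration_years = 3,
      p_open_end = 0.3, # last non-induction interval left open
      mean_n_extra = 1.2
    ),
    fampridine = list(p_user = 0.08, mean_n = 2),
    missingness = list(kfs = 0.2),
    # same-day duplicate / conflicting visits injected to exercise cleaning
    mess = list(dup_rate = 0.01, conflict_rate = 0.004),
    kfs_load = c(
      pyramidal = 0.55, cerebellar = 0.35, brainstem = 0.25, sensory = 0.40,
      sphincteric = 0.30, visual = 0.20, cerebral = 0.20, ambulatory = 0.45
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown sim_config field(s): ", paste(unknown, collapse = ", ")),
      class = "msprog_config_error"
    )
  }
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      modifyList(cfg[[nm]], dots[[nm]])
    } else {
      dots[[nm]]
    }
  }
  validate_sim_config(cfg)
  structure(cfg, class = "ms_sim_config")
}

validate_sim_config <- function(cfg) {
  ok <- cfg$n_patients >= 1 && cfg$n_centers >= 1 &&
    cfg$visit_rate > 0 &&
    all(cfg$course_mix >= 0) && abs(sum(cfg$course_mix) - 1) < 1e-8 &&
    cfg$risk$base_rate > 0 && cfg$risk$base_rate < 1 &&
    cfg$disease_duration$mean > 0 && cfg$disease_duration$sd > 0
  if (!ok) {
    abort("invalid simulation configuration", class = "msprog_config_error")
  }
  invisible(cfg)
}

rtrunc_norm <- function(n, mean, sd, min, max) {
  pmin(pmax(rnorm(n, mean, sd), min), max)
}

# Ground-truth logistic risk law: probability of a sustained progression
# step over the nominal outcome horizon, as a function of the current
# history summaries. The EDSS term saturates at 7.5, and the risk vanishes
# at the top of the scale where no further worsening is expressible.
risk_prob <- function(risk, edss, relapse_rate, sp, pp) {
  p <- plogis(
    qlogis(risk$base_rate) +
      risk$beta[["edss"]] * (pmin(edss, 7.5) - risk$center[["edss"]]) +
      risk$beta[["relapse_rate"]] * (relapse_rate - risk$center[["relapse_rate"]]) +
      risk$beta[["sp"]] * sp + risk$beta[["pp"]] * pp
  )
  ifelse(edss >= 9.75, 0, p)
}

# Equivalent step intensity (per year), held constant between visits.
risk_lambda <- function(risk, edss, relapse_rate, sp, pp) {
  -log(1 - risk_prob(risk, edss, relapse_rate, sp, pp)) / risk$horizon_years
}

#' Simulate a synthetic MS registry cohort
#'
#' Generates the six relational tables of an `ms_cohort` under the model
#' described in [sim_config()]: irregular visit schedules, a bounded
#' half-point EDSS random walk with course-dependent drift, transient
#' post-relapse EDSS bumps that decay within about three months, sustained
#' progression steps driven by the known risk law, treatment histories with
#' efficacy-class policy, and realistic missingness. The generator never
#' computes progression labels itself — labels are obtained by running
#' [enumerate_episodes()] on the generated tables — but it stores its latent
#' step intensities so that [true_episode_risk()] can score any episode.
#'
#' @param config a `ms_sim_config` from [sim_config()].
#' @return an `ms_cohort` carrying a `latent` attribute (tibble with one row
#'   per inter-visit interval: `patient_id`, `interval_start`,
#'   `interval_end`, `lambda`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  ids <- sprintf("P%05d", seq_len(n))
  center_w <- exp(rnorm(cfg$n_centers, 0, 1.1))
  center_ids <- sprintf("C%03d", seq_len(cfg$n_centers))
  centers <- sample(center_ids, n, replace = TRUE, prob = center_w / sum(center_w))

  is_cis <- runif(n) < cfg$cis_rate
  course_last <- sample(names(cfg$course_mix), n, replace = TRUE, prob = cfg$course_mix)
  course_last[is_cis] <- "CIS"

  sex <- ifelse(runif(n) < cfg$sex_female, "F", "M")
  onset_age <- rtrunc_norm(
    n, cfg$onset_age$mean, cfg$onset_age$sd, cfg$onset_age$min, cfg$onset_age$max
  )
  dd <- cfg$disease_duration
  duration <- pmin(pmax(
    rgamma(n, shape = (dd$mean / dd$sd)^2, scale = dd$sd^2 / dd$mean),
    dd$min
  ), dd$max)

  last_date <- cfg$extraction_date - round(runif(n, 0, 365))
  onset_date <- last_date - round(duration * DAYS_PER_YEAR)
  birth_date <- onset_date - round(onset_age * DAYS_PER_YEAR)
  diagnosis_date <- pmin(onset_date + round(runif(n, 0, 730)), last_date)

  edu_missing <- runif(n) < cfg$education$p_missing
  education <- ifelse(
    edu_missing, NA_character_,
    ifelse(runif(n) < cfg$education$p_higher_observed, "higher", "no_higher")
  )
  fs <- cfg$first_symptom
  symptom <- ifelse(
    runif(n) < fs$p_missing, NA_character_,
    sample(names(fs$probs), n, replace = TRUE, prob = fs$probs / sum(fs$probs))
  )

  patients <- tibble(
    patient_id = ids, center_id = centers, sex = sex,
    birth_date = birth_date, ms_onset_date = onset_date,
    diagnosis_date = diagnosis_date, education = education,
    first_symptom = symptom
  )

  acc <- list(
    visits = vector("list", n), relapses = vector("list", n),
    treatments = vector("list", n), courses = vector("list", n),
    fampridine = vector("list", n), latent = vector("list", n)
  )

  for (i in seq_len(n)) {
    one <- simulate_patient(
      cfg,
      id = ids[i], course_last = course_last[i],
      onset = onset_date[i], last = last_date[i]
    )
    for (nm in names(one)) acc[[nm]][[i]] <- one[[nm]]
  }

  cohort <- ms_cohort(
    patients = patients,
    visits = list_rbind(acc$visits),
    relapses = list_rbind(acc$relapses),
    treatments = list_rbind(acc$treatments),
    courses = list_rbind(acc$courses),
    fampridine = list_rbind(acc$fampridine),
    extraction_date = cfg$extraction_date,
    latent = list_rbind(acc$latent)
  )
  attr(cohort, "sim_config") <- cfg
  cohort
}

# One patient's longitudinal records. Sequential because the EDSS walk, the
# relapse bumps and the sustained progression steps all feed back into the
# step intensity through the current history summaries.
simulate_patient <- function(cfg, id, course_last, onset, last) {
  entry <- onset + round(runif(1, 90, 1000))
  if (entry > last - 365) entry <- max(onset + 30, last - 365)

  # irregular visit schedule
  mean_gap <- DAYS_PER_YEAR / cfg$visit_rate
  gaps <- pmax(cfg$min_gap_days, rexp(
    ceiling(as.numeric(last - entry) / mean_gap * 2.5) + 8, 1 / mean_gap
  ))
  dates <- entry + cumsum(round(gaps))
  dates <- c(entry, dates[dates <= last])
  nv <- length(dates)

  # course records
  if (course_last == "SP") {
    conv <- entry + round(runif(1, 0.45, 0.85) * as.numeric(last - entry))
    courses <- tibble(
      patient_id = id, course = c("RR", "SP"),
      effective_date = c(entry, conv)
    )
  } else {
    courses <- tibble(patient_id = id, course = course_last, effective_date = entry)
  }
  sp_from <- if (course_last == "SP") courses$effective_date[2] else as.Date(NA)

  # relapses over [onset, last] (time-varying thinned Poisson)
  rl <- cfg$relapse
  progressive <- course_last %in% c("PP", "CIS")
  horizon_y <- as.numeric(last - onset) / DAYS_PER_YEAR
  rate_at <- function(ty) { # ty: years since onset
    d <- onset + ty * DAYS_PER_YEAR
    in_sp <- !is.na(sp_from) & d >= sp_from
    ifelse(progressive | in_sp, rl$rate_progressive,
      rl$rate_rr * exp(-rl$decay * ty)
    )
  }
  rmax <- max(rl$rate_rr, rl$rate_progressive)
  n_cand <- rpois(1, rmax * horizon_y)
  cand <- sort(runif(n_cand, 0, horizon_y))
  keep <- runif(n_cand) < rate_at(cand) / rmax
  relapse_dates <- onset + round(cand[keep] * DAYS_PER_YEAR)
  nr <- length(relapse_dates)
  pos <- matrix(FALSE, nr, length(RELAPSE_POSITIONS))
  if (nr > 0) {
    for (r in seq_len(nr)) {
      k <- sample(1:2, 1, prob = c(0.8, 0.2))
      pos[r, sample(length(RELAPSE_POSITIONS), k)] <- TRUE
    }
  }
  relapses <- as_tibble(setNames(as.data.frame(pos), POS_COLS)) |>
    mutate(patient_id = id, onset_date = relapse_dates, .before = 1)
  bump_size <- runif(nr, rl$bump_range[1], rl$bump_range[2])

  # EDSS walk with sustained steps from the risk law
  wk <- cfg$edss_walk
  start_par <- if (course_last == "PP") wk$start$PP else wk$start$RR
  level <- snap_edss(rnorm(1, start_par[["mean"]], start_par[["sd"]]))
  floor_lvl <- 0
  edss <- numeric(nv)
  lambdas <- numeric(nv) # intensity over (dates[i], dates[i+1]]
  rel_num <- as.numeric(relapse_dates)
  course_v <- course_at(courses, dates)

  pending_raise <- 0 # level raise from steps matured since previous visit
  for (i in seq_len(nv)) {
    if (i > 1) {
      dt <- as.numeric(dates[i] - dates[i - 1]) / DAYS_PER_YEAR
      drift <- unname(wk$drift[course_v[i]])
      if (is.na(drift)) drift <- 0
      level <- level + drift * dt + rnorm(1, 0, wk$volatility * sqrt(dt))
    }
    level <- max(level + pending_raise, floor_lvl)
    if (pending_raise > 0) floor_lvl <- level
    pending_raise <- 0
    level <- min(max(level, 0), 9.5)

    bump <- 0
    if (nr > 0) {
      dtb <- as.numeric(dates[i]) - rel_num
      act <- dtb >= 0 & dtb <= rl$bump_decay_days
      if (any(act)) bump <- sum(bump_size[act] * (1 - dtb[act] / rl$bump_decay_days))
    }
    edss[i] <- snap_edss(level + bump)

    # intensity for the interval after this visit, from current summaries
    fy <- max(as.numeric(dates[i] - dates[1]) / DAYS_PER_YEAR, 1e-9)
    rrate <- if (i == 1) 0 else sum(rel_num < as.numeric(dates[i])) / fy
    lam <- risk_lambda(
      cfg$risk, edss[i], min(rrate, 3),
      as.numeric(course_v[i] == "SP"), as.numeric(course_v[i] == "PP")
    )
    lambdas[i] <- lam
    if (i < nv) {
      dt_next <- as.numeric(dates[i + 1] - dates[i]) / DAYS_PER_YEAR
      n_steps <- rpois(1, lam * dt_next)
      if (n_steps > 0) {
        thr <- progression_threshold(edss[i])
        target <- edss[i] + thr + cfg$risk$step_margin
        pending_raise <- max(target - level, 0)
      }
    }
  }

  # KFS correlated with EDSS, with missingness
  kfs <- sapply(cfg$kfs_load, function(wl) {
    v <- pmin(pmax(round(wl * edss + rnorm(nv, 0, 0.6)), 0), 6)
    v[runif(nv) < cfg$missingness$kfs] <- NA
    v
  })
  if (nv == 1) kfs <- matrix(kfs, nrow = 1, dimnames = list(NULL, names(cfg$kfs_load)))
  visits <- as_tibble(as.data.frame(kfs)) |>
    setNames(KFS_COLS) |>
    mutate(patient_id = id, visit_date = dates, edss = edss, .before = 1)

  # inject same-day duplicates / conflicts (cleaning-path exercise)
  ms <- cfg$mess
  if (nv > 1 && runif(1) < ms$dup_rate * nv) {
    visits <- bind_rows(visits, visits[sample(nv, 1), ])
  }
  if (nv > 2 && runif(1) < ms$conflict_rate * nv) {
    row <- visits[sample(nv, 1), ]
    row$edss <- snap_edss(row$edss + 1)
    visits <- bind_rows(visits, row)
  }

  # treatments
  dmt <- cfg$dmt
  treatments <- tibble(
    patient_id = character(), dmt_name = character(),
    start_date = as.Date(character()), end_date = as.Date(character())
  )
  if (runif(1) >= dmt$p_never) {
    n_ep <- 1 + rpois(1, dmt$mean_n_extra)
    t_cur <- entry + round(runif(1, 0, 730))
    rows <- list()
    for (e in seq_len(n_ep)) {
      if (t_cur >= last) break
      cls <- sample(names(dmt$class_probs), 1, prob = dmt$class_probs)
      name <- sample(DMT_VOCAB[[cls]], 1)
      dur <- round((rexp(1, 1 / dmt$mean_duration_years) + 0.25) * DAYS_PER_YEAR)
      end <- min(t_cur + dur, last)
      induction_start_only <- cls == "high_induction"
      open <- !induction_start_only && e == n_ep && runif(1) < dmt$p_open_end
      rows[[e]] <- tibble(
        patient_id = id, dmt_name = name, start_date = t_cur,
        end_date = if (induction_start_only || open) as.Date(NA) else end
      )
      # induction DMTs do not occupy the timeline exclusively
      t_cur <- if (induction_start_only) t_cur + 90 else end + round(runif(1, 0, 365))
    }
    treatments <- list_rbind(rows)
  }

  fam <- cfg$fampridine
  fampridine <- if (runif(1) < fam$p_user && as.numeric(last - entry) > 400) {
    nf <- 1 + rpois(1, fam$mean_n - 1)
    tibble(
      patient_id = id,
      date = entry + round(runif(nf, 365, as.numeric(last - entry)))
    )
  } else {
    tibble(patient_id = character(), date = as.Date(character()))
  }

  latent <- tibble(
    patient_id = id,
    visit_date = dates,
    step_risk = 1 - exp(-lambdas * cfg$risk$horizon_years)
  )

  list(
    visits = visits, relapses = relapses, treatments = treatments,
    courses = courses, fampridine = fampridine, latent = latent
  )
}

#' Ground-truth progression risk of simulated episodes
#'
#' For episodes extracted from a simulated cohort, returns the generator's
#' risk law evaluated at the episode baseline: the probability that a
#' sustained progression step arrives within the nominal outcome horizon,
#' a logistic function of the baseline history summaries (EDSS, annualized
#' relapse rate, course). This is the Bayes score attainable from the
#' observation window and enables discrimination-ceiling and
#' parameter-recovery tests.
#'
#' @param cohort a simulated `ms_cohort` (must carry the `latent`
#'   attribute).
#' @param episodes episode tibble from [enumerate_episodes()] (any subset
#'   of rows).
#' @return numeric vector of probabilities, aligned with `episodes` rows.
#' @export
true_episode_risk <- function(cohort, episodes) {
  latent <- attr(cohort, "latent")
  if (is.null(latent)) {
    abort("cohort carries no generator ground truth (latent attribute)",
      class = "msprog_lookup_error"
    )
  }
  miss <- setdiff(unique(episodes$patient_id), unique(latent$patient_id))
  if (length(miss) > 0) {
    abort(sprintf(
      "episodes reference %d patient(s) unknown to this cohort's generator",
      length(miss)
    ), class = "msprog_lookup_error")
  }
  key <- paste(latent$patient_id, as.Date(latent$visit_date))
  idx <- match(paste(episodes$patient_id, as.Date(episodes$t0)), key)
  if (any(is.na(idx))) {
    abort("some episode baselines are unknown to this cohort's generator",
      class = "msprog_lookup_error"
    )
  }
  latent$step_risk[idx]
}
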
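# Canonical episode scenarios (valid and invalid) used both as unit-test
# fixtures and, serialized under inst/extdata/episode_scenarios, by the CLI
# test. Day offsets are relative to each patient's baseline visit at day 0
# (= ORIGIN). One year is ~365.25 days.

fig7_visits <- list(
  # confirmed progression: event at 2y; the EDSS at ~2y5m sits within one
  # month after a relapse and is excluded; the EDSS at 4y confirms.
  confirmed = data.frame(
    day = c(-900, -550, -180, 0, 730, 880, 1461),
    edss = c(3.0, 3.0, 3.0, 3.0, 4.0, 4.0, 4.0)
  ),
  # not enough EDSS measurements in the trailing 3.25 years
  short_history = data.frame(
    day = c(-180, 0, 548, 800, 1100),
    edss = c(3.0, 3.0, 4.0, 4.0, 4.0)
  ),
  # progression but nothing after 2y to confirm with
  unconfirmable = data.frame(
    day = c(-900, -550, -180, 0, 657),
    edss = c(3.0, 3.0, 3.0, 3.0, 4.5)
  ),
  # EDSS decreases after 2y: no confirmed progression (but valid)
  regressed = data.frame(
    day = c(-900, -550, -180, 0, 694, 803),
    edss = c(3.0, 3.0, 3.0, 3.0, 4.0, 3.0)
  ),
  # no progression at 2y: valid without any confirmation
  no_progression = data.frame(
    day = c(-900, -550, -180, 0, 548),
    edss = c(3.0, 3.0, 3.0, 3.0, 3.0)
  )
)

fig7_relapses <- list(confirmed = c(875))

fig7_expected <- tibble::tibble(
  patient_id = c(
    "confirmed", "short_history", "unconfirmable", "regressed",
    "no_progression"
  ),
  w = c(1L, 1L, 1L, 1L, 0L),
  w_c = c(1L, 1L, NA, 0L, 0L),
  validity = c(
    "valid", "invalid_insufficient_history", "invalid_unconfirmable",
    "valid", "valid"
  )
)

fig7_cohort <- function() {
  make_cohort(fig7_visits, relapses = fig7_relapses)
}

# baseline episodes (t0 at day 0 = ORIGIN) extracted from the full candidate
# table
fig7_baseline_episodes <- function(episodes) {
  dplyr::filter(episodes, .data$t0 == ORIGIN) |>
    dplyr::arrange(match(.data$patient_id, fig7_expected$patient_id))
}
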
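#' Efficacy class of a disease-modifying therapy
#'
#' Maps DMT names (case-insensitive) to efficacy classes: low
#' (Interferons, Teriflunomide, Glatiramer, Azathioprine, Methotrexate),
#' moderate (Fingolimod, Dimethyl-Fumarate, Cladribine, Siponimod,
#' Daclizumab), high (Alemtuzumab, Rituximab, Ocrelizumab, Natalizumab), and
#' the highly active induction DMTs Mitoxantrone and Cyclophosphamide, which
#' are coded separately because they can be administered in combination with
#' another DMT.
#'
#' @param dmt_name character vector of DMT names.
#' @return factor-like character vector with levels
#'   `low`, `moderate`, `high`, `high_induction`.
#' @export
categorize_dmt <- function(dmt_name) {
  vocab <- unlist(DMT_VOCAB, use.names = FALSE)
  classes <- rep(names(DMT_VOCAB), lengths(DMT_VOCAB))
  idx <- match(tolower(dmt_name), tolower(vocab))
  if (any(is.na(idx) & !is.na(dmt_name))) {
    bad <- unique(dmt_name[is.na(idx) & !is.na(dmt_name)])
    abort(sprintf(
      "unknown DMT name(s): %s\naccepted names: %s",
      paste(bad, collapse = ", "), paste(vocab, collapse = ", ")
    ), class = "msprog_vocab_error")
  }
  classes[idx]
}

# DMTs with induction semantics whose administration nevertheless ends when a
# new DMT is started (unlike Mitoxantrone/Cyclophosphamide, which keep
# start-only records and may overlap other DMTs).
INDUCTION_CLOSEABLE <- c("Alemtuzumab", "Cladribine")

#' Impute missing treatment end dates
#'
#' Only one non-induction DMT is assumed active at a time: an open-ended
#' record is closed at the start date of the patient's next non-induction
#' DMT. Mitoxantrone and Cyclophosphamide keep start-only semantics and may
#' overlap other treatments. Records whose imputed end precedes their start
#' are dropped with a warning.
#'
#' @param records treatments tibble (`patient_id`, `dmt_name`, `start_date`,
#'   `end_date`).
#' @return the records with `end_date` imputed and an `efficacy_class`
#'   column appended.
#' @export
impute_treatment_ends <- function(records) {
  if (nrow(records) == 0) {
    return(mutate(records, efficacy_class = character(0)))
  }
  records <- records |>
    mutate(efficacy_class = categorize_dmt(.data$dmt_name)) |>
    arrange(.data$patient_id, .data$start_date)
  out <- records |>
    group_by(.data$patient_id) |>
    group_modify(function(df, key) {
      excl <- df$efficacy_class == "high_induction"
      seq_starts <- df$start_date[!excl]
      next_start <- function(s) {
        later <- seq_starts[seq_starts > s]
        if (length(later) == 0) as.Date(NA) else min(later)
      }
      for (i in which(!excl)) {
        if (is.na(df$end_date[i])) {
          df$end_date[i] <- next_start(df$start_date[i])
        } else {
          # a new DMT start also terminates a recorded-but-later end
          nxt <- next_start(df$start_date[i])
          if (!is.na(nxt) && nxt < df$end_date[i]) df$end_date[i] <- nxt
        }
      }
      bad <- !is.na(df$end_date) & df$end_date < df$start_date
      if (any(bad)) {
        warn(sprintf(
          "dropping %d treatment record(s) with end before start", sum(bad)
        ))
        df <- df[!bad, , drop = FALSE]
      }
      df
    }) |>
    ungroup()
  out
}
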
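KFS_NAMES <- c(
  "pyramidal", "cerebellar", "brainstem", "sensory",
  "sphincteric", "visual", "cerebral", "ambulatory"
)
KFS_COLS <- paste0("kfs_", KFS_NAMES)

RELAPSE_POSITIONS <- c(
  "pyramidal_tract", "brainstem", "bowel_bladder",
  "cerebellum", "visual_function", "sensory"
)
POS_COLS <- paste0("pos_", RELAPSE_POSITIONS)

COHORT_TABLES <- c(
  "patients", "visits", "relapses", "treatments", "courses", "fampridine"
)

#' Construct a relational MS registry cohort
#'
#' Bundles the six registry tables used throughout the pipeline into a single
#' `ms_cohort` object: patient-level demographics, EDSS/KFS visits, relapses,
#' disease-modifying-therapy (DMT) intervals, MS course records, and
#' Fampridine administrations.
#'
#' Expected columns:
#' * `patients`: `patient_id`, `center_id`, `sex` (`"F"`/`"M"`), `birth_date`,
#'   `ms_onset_date`, `diagnosis_date`, `education` (`"higher"`,
#'   `"no_higher"`, or `NA`), `first_symptom` (`"supratentorial"`,
#'   `"optic_pathways"`, `"brainstem"`, `"spinal_cord"`, or `NA`).
#' * `visits`: `patient_id`, `visit_date`, `edss`, and the eight
#'   Kurtzke functional-system scores `kfs_pyramidal` ... `kfs_ambulatory`
#'   (integer 0--6 or `NA`).
#' * `relapses`: `patient_id`, `onset_date`, and logical position flags
#'   `pos_pyramidal_tract` ... `pos_sensory`.
#' * `treatments`: `patient_id`, `dmt_name`, `start_date`, `end_date`
#'   (`NA` when the interval is open).
#' * `courses`: `patient_id`, `course` (`"CIS"`, `"RR"`, `"SP"`, `"PP"`),
#'   `effective_date`.
#' * `fampridine`: `patient_id`, `date`.
#'
#' @param patients,visits,relapses,treatments,courses,fampridine data frames
#'   with the columns listed above. `fampridine` may be omitted.
#' @param extraction_date the registry extraction date; records after this
#'   date are treated as invalid by [clean_cohort()].
#' @param latent optional tibble of generator ground truth (see
#'   [simulate_cohort()]); kept as metadata, never used by the pipeline
#'   itself.
#' @return an object of class `ms_cohort`: a named list of tibbles with
#'   attributes `extraction_date` and (optionally) `latent`.
#' @seealso [simulate_cohort()], [clean_cohort()], [read_cohort()]
#' @export
ms_cohort <- function(patients, visits, relapses, treatments, courses,
                      fampridine = NULL, extraction_date = NULL,
                      latent = NULL) {
  if (is.null(fampridine)) {
    fampridine <- tibble(patient_id = character(), date = as.Date(character()))
  }
  x <- list(
    patients = as_tibble(patients),
    visits = as_tibble(visits),
    relapses = as_tibble(relapses),
    treatments = as_tibble(treatments),
    courses = as_tibble(courses),
    fampridine = as_tibble(fampridine)
  )
  if (is.null(extraction_date)) {
    dates <- suppressWarnings(c(
      max(x$visits$visit_date, na.rm = TRUE),
      max(x$courses$effective_date, na.rm = TRUE)
    ))
    extraction_date <- max(as.Date(dates[is.finite(dates)], origin = "1970-01-01"))
  }
  structure(
    x,
    extraction_date = as.Date(extraction_date),
    latent = latent,
    class = "ms_cohort"
  )
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat("<ms_cohort>\n")
  cat(sprintf(
    "  %d patients, %d centers, %d visits, %d relapses, %d treatment records\n",
    nrow(x$patients), dplyr::n_distinct(x$patients$center_id),
    nrow(x$visits), nrow(x$relapses), nrow(x$treatments)
  ))
  cat(sprintf("  extraction date: %s\n", attr(x, "extraction_date")))
  if (!is.null(attr(x, "latent"))) {
    cat("  carries generator ground truth (latent risk)\n")
  }
  excl <- attr(x, "exclusions")
  if (!is.null(excl)) cat("  cleaned (see attr(., 'exclusions'))\n")
  invisible(x)
}

# Basic schema check used at entry points that accept user CSVs.
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ms_cohort"))
  need <- list(
    patients = c(
      "patient_id", "center_id", "sex", "birth_date", "ms_onset_date",
      "diagnosis_date", "education", "first_symptom"
    ),
    visits = c("patient_id", "visit_date", "edss", KFS_COLS),
    relapses = c("patient_id", "onset_date", POS_COLS),
    treatments = c("patient_id", "dmt_name", "start_date", "end_date"),
    courses = c("patient_id", "course", "effective_date"),
    fampridine = c("patient_id", "date")
  )
  for (tab in names(need)) {
    missing <- setdiff(need[[tab]], names(cohort[[tab]]))
    if (length(missing) > 0) {
      abort(sprintf(
        "cohort table '%s' is missing column(s): %s",
        tab, paste(missing, collapse = ", ")
      ), class = "msprog_format_error")
    }
  }
  bad <- cohort$visits$edss
  bad <- bad[!is.na(bad)]
  if (any(!is_edss(bad))) {
    abort("visits table contains EDSS values off the half-point grid",
      class = "msprog_format_error"
    )
  }
  invisible(cohort)
}

#' Write a cohort to a directory of CSV tables
#'
#' Writes one CSV per table (`patients.csv`, `visits.csv`, `relapses.csv`,
#' `treatments.csv`, `courses.csv`, `fampridine.csv`) with ISO-8601 dates.
#' Generator ground truth, when present, is written to `latent.csv` so that
#' simulated cohorts round-trip losslessly.
#'
#' @param cohort an `ms_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  validate_cohort(cohort)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in COHORT_TABLES) {
    readr::write_csv(cohort[[tab]], file.path(dir, paste0(tab, ".csv")))
  }
  meta <- list(extraction_date = as.character(attr(cohort, "extraction_date")))
  jsonlite::write_json(meta, file.path(dir, "cohort.json"), auto_unbox = TRUE)
  if (!is.null(attr(cohort, "latent"))) {
    readr::write_csv(attr(cohort, "latent"), file.path(dir, "latent.csv"))
  }
  invisible(dir)
}

#' Read a cohort from a directory of CSV tables
#'
#' Inverse of [write_cohort()]. Dates are parsed as ISO-8601.
#'
#' @param dir directory containing the cohort CSV tables.
#' @return an `ms_cohort`.
#' @export
read_cohort <- function(dir) {
  read1 <- function(name, required = TRUE) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) {
      if (required) {
        abort(sprintf("missing cohort table: %s", path),
          class = "msprog_format_error"
        )
      }
      return(NULL)
    }
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  tabs <- lapply(setNames(COHORT_TABLES, COHORT_TABLES), function(nm) {
    read1(nm, required = !nm %in% "fampridine")
  })
  meta_path <- file.path(dir, "cohort.json")
  extraction <- if (file.exists(meta_path)) {
    as.Date(jsonlite::read_json(meta_path)$extraction_date)
  } else {
    NULL
  }
  latent_path <- file.path(dir, "latent.csv")
  latent <- if (file.exists(latent_path)) {
    readr::read_csv(latent_path, show_col_types = FALSE, progress = FALSE)
  } else {
    NULL
  }
  cohort <- ms_cohort(
    tabs$patients, tabs$visits, tabs$relapses, tabs$treatments, tabs$courses,
    fampridine = tabs$fampridine, extraction_date = extraction, latent = latent
  )
  validate_cohort(cohort)
  cohort
}
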
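#' @import dplyr
#' @import tibble
#' @importFrom rlang .data abort %||%
#' @importFrom stats median quantile rnorm rbinom rpois rlnorm runif qnorm
#'   plogis qlogis setNames complete.cases sd
#' @importFrom utils head tail
NULL

# -- vocabulary ---------------------------------------------------------------

#' Recognised adverse-event types
#'
#' Event vocabulary used throughout the package: neutropenic fever (fever
#' > 38.2 C during chemotherapy-induced neutropenia), mild renal impairment
#' (serum creatinine > 1.2 mg/dL prompting IV fluids), erythrocyte
#' transfusion, nausea/diarrhea, and acute kidney injury.
#'
#' @return Character vector of event type codes.
#' @export
event_types <- function() {
  c("neutropenic_fever", "mild_renal_impairment", "transfusion",
    "nausea_diarrhea", "aki")
}

#' Mobilization regimens and their therapy durations
#'
#' Three mobilization chemotherapy regimens are modelled: cyclophosphamide
#' 4 g/m2 over 2 days, etoposide plus cyclophosphamide over 3 days, and
#' etoposide alone over 4 days.
#'
#' @return Named integer vector mapping regimen code to therapy duration
#'   in days.
#' @export
regimen_durations <- function() {
  c(cyclo_4000 = 2L, etoposide_cyclo = 3L, etoposide_alone = 4L)
}

# lab panel measured at admission and repeated on days 3 and 5
lab_panel <- function() {
  c("creatinine_mg_dl", "ldh_u_l", "hemoglobin_g_dl",
    "platelets_per_nl", "crp_mg_l")
}

longitudinal_cols <- function() {
  as.vector(outer(c("day3_", "day5_"), lab_panel(), paste0))
}

patient_cols <- function() {
  c("patient_id", "admission_offset", "regimen", "therapy_duration_days",
    "leukopenia_onset_day", "leukopenia_duration_days",
    "scc_start_day", "scc_duration_days", "scc_success", "post_scc_days",
    "age_years", "sex", "creatinine_mg_dl", "ldh_u_l", "hemoglobin_g_dl",
    "platelets_per_nl", "crp_mg_l", "calcium_mmol_l", "albumin_g_dl",
    "prior_ce_therapy", "prior_lines", "full_dose_flag",
    "cyclo_flag", "ce_flag", "etoposide_flag", "gcsf_dose_flag",
    longitudinal_cols())
}

event_cols <- function() {
  c("patient_id", "event_type", "onset_day", "ctcae_grade",
    "requires_hospitalization", "germ_detected")
}

# -- construction and validation ----------------------------------------------

#' Assemble a cohort from patient and event tables
#'
#' A cohort couples a per-patient timeline table (one row per patient, day
#' axis anchored at therapy start = day 0) with a long-format adverse-event
#' table keyed by `patient_id`. All structural invariants are checked.
#'
#' @param patients Data frame of patient timelines and covariates; see
#'   [read_cohort()] for the column contract.
#' @param events Data frame of adverse events (`patient_id`, `event_type`,
#'   `onset_day`, `ctcae_grade`, `requires_hospitalization`,
#'   `germ_detected`).
#' @param provenance One of `"fixture"`, `"synthetic"`, `"user"`.
#' @param seed Integer seed the cohort was generated with, or `NULL`.
#'
#' @return An object of class `scm_cohort`: a list with elements `patients`
#'   (tibble), `events` (tibble), `provenance`, `seed`.
#' @export
new_cohort <- function(patients, events, provenance = "user", seed = NULL) {
  patients <- as_tibble(patients)
  events <- as_tibble(events)
  cohort <- structure(
    list(patients = patients, events = events,
         provenance = provenance, seed = seed),
    class = "scm_cohort")
  validate_cohort(cohort)
  # canonical column order so persistence and comparison are stable
  cohort$patients <- select(patients, all_of(patient_cols()),
                            everything())
  cohort$events <- if (nrow(events) == 0) empty_events() else
    select(events, all_of(event_cols()), everything())
  cohort
}

#' @export
print.scm_cohort <- function(x, ...) {
  cat(sprintf("<scm_cohort> %d patients, %d adverse events (%s)\n",
              nrow(x$patients), nrow(x$events), x$provenance))
  n_sae <- x$events |>
    filter(.data$requires_hospitalization) |>
    distinct(.data$patient_id) |>
    nrow()
  cat(sprintf("  patients with >=1 hospitalizing (severe) AE: %d\n", n_sae))
  invisible(x)
}

#' Validate cohort invariants
#'
#' Checks the schema (missing columns raise an error naming the column) and
#' the domain invariants: unique patient ids; admission on or before therapy
#' start; regimen/therapy-duration consistency (2/3/4 days); event onsets in
#' \[-4, 30\]; successful collections starting on days 10--19; leukopenia
#' duration only with a recorded onset; positive lab values.
#'
#' @param cohort An `scm_cohort`.
#' @return The cohort, invisibly; errors on any violation.
#' @export
validate_cohort <- function(cohort) {
  p <- cohort$patients
  e <- cohort$events
  for (col in patient_cols()) {
    if (!col %in% names(p)) {
      abort(sprintf("patients table is missing required column '%s'", col),
            class = "scm_schema_error")
    }
  }
  for (col in event_cols()) {
    if (!col %in% names(e)) {
      abort(sprintf("events table is missing required column '%s'", col),
            class = "scm_schema_error")
    }
  }
  if (nrow(p) == 0) abort("cohort is empty", class = "scm_validation_error")
  if (anyDuplicated(p$patient_id)) {
    abort(sprintf("duplicated patient_id: %s",
                  p$patient_id[duplicated(p$patient_id)][1]),
          class = "scm_validation_error")
  }
  bad <- function(ids, what) {
    abort(sprintf("invariant violated (%s) for patient_id: %s",
                  what, paste(head(unique(ids), 3), collapse = ", ")),
          class = "scm_validation_error")
  }
  if (any(p$admission_offset > 0)) {
    bad(p$patient_id[p$admission_offset > 0], "admission_offset must be <= 0")
  }
  durs <- regimen_durations()
  if (any(!p$regimen %in% names(durs))) {
    bad(p$patient_id[!p$regimen %in% names(durs)], "unknown regimen")
  }
  mism <- p$therapy_duration_days != unname(durs[p$regimen])
  if (any(mism)) bad(p$patient_id[mism], "regimen/therapy_duration mismatch")
  ok_scc <- !p$scc_success |
    (!is.na(p$scc_start_day) & p$scc_start_day >= 10 & p$scc_start_day <= 19)
  if (any(!ok_scc)) {
    bad(p$patient_id[!ok_scc],
        "successful collection requires scc_start_day in [10, 19]")
  }
  orphan_dur <- !is.na(p$leukopenia_duration_days) &
    is.na(p$leukopenia_onset_day)
  if (any(orphan_dur)) {
    bad(p$patient_id[orphan_dur], "leukopenia duration without onset")
  }
  if (any(!is.na(p$post_scc_days) & p$post_scc_days < 0)) {
    bad(p$patient_id[!is.na(p$post_scc_days) & p$post_scc_days < 0],
        "post_scc_days must be >= 0")
  }
  if (any(!p$sex %in% c("M", "F"))) {
    bad(p$patient_id[!p$sex %in% c("M", "F")], "sex must be 'M' or 'F'")
  }
  for (lab in c(lab_panel(), "calcium_mmol_l", "albumin_g_dl",
                longitudinal_cols())) {
    neg <- !is.na(p[[lab]]) & p[[lab]] <= 0
    if (any(neg)) bad(p$patient_id[neg], sprintf("non-positive %s", lab))
  }
  if (nrow(e) > 0) {
    if (any(!e$event_type %in% event_types())) {
      bad(e$patient_id[!e$event_type %in% event_types()],
          "unknown event_type")
    }
    out <- e$onset_day < -4 | e$onset_day > 30
    if (any(out)) bad(e$patient_id[out], "onset_day outside [-4, 30]")
    okg <- is.na(e$ctcae_grade) | (e$ctcae_grade >= 1 & e$ctcae_grade <= 5)
    if (any(!okg)) bad(e$patient_id[!okg], "ctcae_grade outside 1-5")
    unk <- !e$patient_id %in% p$patient_id
    if (any(unk)) bad(e$patient_id[unk], "event for unknown patient_id")
  }
  invisible(cohort)
}

# -- persistence --------------------------------------------------------------

event_col_types <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    event_type = readr::col_character(),
    onset_day = readr::col_integer(),
    ctcae_grade = readr::col_integer(),
    requires_hospitalization = readr::col_logical(),
    germ_detected = readr::col_logical())
}

patient_col_types <- function() {
  int_cols <- c("admission_offset", "therapy_duration_days",
                "leukopenia_onset_day", "leukopenia_duration_days",
                "scc_start_day", "scc_duration_days", "post_scc_days",
                "age_years", "prior_lines")
  lgl_cols <- c("scc_success", "prior_ce_therapy", "full_dose_flag",
                "cyclo_flag", "ce_flag", "etoposide_flag", "gcsf_dose_flag")
  chr_cols <- c("patient_id", "regimen", "sex")
  spec <- lapply(patient_cols(), function(col) {
    if (col %in% int_cols) readr::col_integer()
    else if (col %in% lgl_cols) readr::col_logical()
    else if (col %in% chr_cols) readr::col_character()
    else readr::col_double()
  })
  do.call(readr::cols, setNames(spec, patient_cols()))
}

coerce_patient_types <- function(p) {
  int_cols <- c("admission_offset", "therapy_duration_days",
                "leukopenia_onset_day", "leukopenia_duration_days",
                "scc_start_day", "scc_duration_days", "post_scc_days",
                "age_years", "prior_lines")
  lgl_cols <- c("scc_success", "prior_ce_therapy", "full_dose_flag",
                "cyclo_flag", "ce_flag", "etoposide_flag", "gcsf_dose_flag")
  dbl_cols <- setdiff(patient_cols(),
                      c(int_cols, lgl_cols, "patient_id", "regimen", "sex"))
  p |>
    mutate(across(all_of(int_cols), as.integer),
           across(all_of(lgl_cols), as.logical),
           across(all_of(dbl_cols), as.double)) |>
    select(all_of(patient_cols()))
}

coerce_event_types <- function(e) {
  if (nrow(e) == 0) return(empty_events())
  e |>
    mutate(patient_id = as.character(.data$patient_id),
           event_type = as.character(.data$event_type),
           onset_day = as.integer(.data$onset_day),
           ctcae_grade = as.integer(.data$ctcae_grade),
           requires_hospitalization = as.logical(.data$requires_hospitalization),
           germ_detected = as.logical(.data$germ_detected)) |>
    select(all_of(event_cols()))
}

empty_events <- function() {
  tibble(patient_id = character(), event_type = character(),
         onset_day = integer(), ctcae_grade = integer(),
         requires_hospitalization = logical(), germ_detected = logical())
}

#' Read a cohort from disk
#'
#' Two interchange formats are supported. `"json"` expects a single file
#' with fields `provenance`, `seed`, `patients`, `events`. `"csv"` expects a
#' directory containing `patients.csv` and `events.csv` (plus an optional
#' `meta.json` carrying provenance and seed). Days are integers relative to
#' therapy start (day 0); no calendar dates are accepted.
#'
#' @param path File (json) or directory (csv).
#' @param format `"json"` or `"csv"`; guessed from `path` when omitted.
#' @return A validated [new_cohort()] object; row order is preserved.
#' @export
read_cohort <- function(path, format = c("json", "csv")) {
  if (missing(format)) {
    format <- if (dir.exists(path)) "csv" else "json"
  }
  format <- match.arg(format)
  if (format == "json") {
    if (!file.exists(path)) abort(sprintf("file not found: %s", path))
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    patients <- coerce_patient_types(as_tibble(raw$patients))
    events <- if (is.null(raw$events) || length(raw$events) == 0) {
      empty_events()
    } else {
      coerce_event_types(as_tibble(raw$events))
    }
    new_cohort(patients, events,
               provenance = raw$provenance %||% "user",
               seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed))
  } else {
    pfile <- file.path(path, "patients.csv")
    efile <- file.path(path, "events.csv")
    if (!file.exists(pfile)) abort(sprintf("file not found: %s", pfile))
    if (!file.exists(efile)) abort(sprintf("file not found: %s", efile))
    patients <- readr::read_csv(pfile, col_types = patient_col_types())
    events <- readr::read_csv(efile, col_types = event_col_types())
    if (nrow(events) == 0) events <- empty_events()
    meta <- list(provenance = "user", seed = NULL)
    mfile <- file.path(path, "meta.json")
    if (file.exists(mfile)) meta <- jsonlite::fromJSON(mfile)
    new_cohort(patients, events, provenance = meta$provenance %||% "user",
               seed = if (is.null(meta$seed)) NULL else as.integer(meta$seed))
  }
}

#' Write a cohort to disk
#'
#' Inverse of [read_cohort()]: persistence is lossless at field level for
#' both formats, including missing values.
#'
#' @param cohort An `scm_cohort`.
#' @param path Target file (json) or directory (csv; created if needed).
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("json", "csv")) {
  format <- match.arg(format)
  validate_cohort(cohort)
  if (format == "json") {
    payload <- list(provenance = cohort$provenance, seed = cohort$seed,
                    patients = cohort$patients, events = cohort$events)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null")
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    readr::write_csv(cohort$patients, file.path(path, "patients.csv"),
                     na = "")
    readr::write_csv(cohort$events, file.path(path, "events.csv"), na = "")
    jsonlite::write_json(list(provenance = cohort$provenance,
                              seed = cohort$seed),
                         file.path(path, "meta.json"),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

# -- severe adverse events on the day axis ------------------------------------

#' First severe-adverse-event day per patient
#'
#' The first SAE day is the minimum onset over a patient's events flagged
#' `requires_hospitalization`; `NA` when the patient has no such event.
#' Invariant to the ordering of the event table.
#'
#' @param cohort An `scm_cohort`.
#' @return Tibble with `patient_id` and `first_sae_day` (integer or `NA`),
#'   one row per patient in cohort order.
#' @export
first_sae_day <- function(cohort) {
  hosp <- filter(cohort$events, .data$requires_hospitalization)
  sae <- if (nrow(hosp) == 0) {
    tibble(patient_id = character(), first_sae_day = integer())
  } else {
    hosp |>
      group_by(.data$patient_id) |>
      summarise(first_sae_day = min(.data$onset_day), .groups = "drop")
  }
  cohort$patients |>
    select("patient_id") |>
    left_join(sae, by = "patient_id") |>
    mutate(first_sae_day = as.integer(.data$first_sae_day))
}

#' Flag patients with an early severe adverse event
#'
#' Early SAEs are severe events within 72 h of therapy start, i.e. first SAE
#' onset on days 0--2 for the default 3-day window (half-open `[0, window)` at
#' integer day resolution). The window can alternatively be anchored at
#' hospital admission, in which case onset days are measured relative to the
#' admission day.
#'
#' @param cohort An `scm_cohort`.
#' @param window_days Window length in days (default 3 = 72 h).
#' @param anchor `"therapy_start"` (default, day 0) or `"admission"`.
#' @return Tibble with `patient_id` and logical `early_sae`.
#' @export
is_early_sae <- function(cohort, window_days = 3,
                         anchor = c("therapy_start", "admission")) {
  anchor <- match.arg(anchor)
  out <- first_sae_day(cohort) |>
    left_join(select(cohort$patients, "patient_id", "admission_offset"),
              by = "patient_id")
  rel <- if (anchor == "therapy_start") {
    out$first_sae_day
  } else {
    out$first_sae_day - out$admission_offset
  }
  out |>
    mutate(early_sae = !is.na(.data$first_sae_day) & rel < window_days) |>
    select("patient_id", "early_sae")
}
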
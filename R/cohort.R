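#' Read a patient cohort from delimited text files
#'
#' Loads the two-table cohort format: a patient table and a long glucose
#' table, one row per measurement.  Measurements beyond the 14-day
#' monitoring horizon (336 h after ICU admission) are dropped with a
#' message; traces are returned sorted by time within patient.
#'
#' `patients.csv` columns: `patient_id, group, dci_onset_h, age, sex,
#' mfisher, hunt_hess, saps2` with `group` one of `"DCI"`/`"noDCI"` and
#' `dci_onset_h` empty exactly for the no-DCI group.
#' `glucose.csv` columns: `patient_id, time_h, glucose_mgdl`.
#'
#' @param patients_path path to the patient metadata CSV.
#' @param glucose_path path to the glucose measurement CSV.
#' @return A list with elements `patients` and `glucose` (tibbles).
#' @export
read_cohort <- function(patients_path, glucose_path) {
  patients <- readr::read_csv(
    patients_path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      group = readr::col_character(),
      dci_onset_h = readr::col_double(),
      age = readr::col_double(),
      sex = readr::col_character(),
      mfisher = readr::col_integer(),
      hunt_hess = readr::col_integer(),
      saps2 = readr::col_integer()
    ),
    progress = FALSE
  )
  glucose <- readr::read_csv(
    glucose_path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      time_h = readr::col_double(),
      glucose_mgdl = readr::col_double()
    ),
    progress = FALSE
  )
  validate_cohort(patients, glucose)
}

#' Assemble and validate a cohort from in-memory tables
#'
#' Applies the same checks and normalisation as [read_cohort()]: schema and
#' range validation, truncation at the monitoring horizon, and time-sorting
#' within patient.
#'
#' @param patients data frame of patient metadata.
#' @param glucose data frame of glucose measurements.
#' @return A list with elements `patients` and `glucose`.
#' @export
validate_cohort <- function(patients, glucose) {
  patients <- tibble::as_tibble(patients)
  glucose <- tibble::as_tibble(glucose)

  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in patient table")
  }
  if (!all(patients$group %in% c("DCI", "noDCI"))) {
    stop("group must be 'DCI' or 'noDCI'")
  }
  is_dci <- patients$group == "DCI"
  if (any(is_dci & !is.finite(patients$dci_onset_h))) {
    stop("dci_onset_h missing for a DCI patient")
  }
  if (any(!is_dci & !is.na(patients$dci_onset_h))) {
    stop("dci_onset_h must be empty for no-DCI patients")
  }
  bad_onset <- is_dci &
    (patients$dci_onset_h <= 0 | patients$dci_onset_h > MONITORING_MAX_H)
  if (any(bad_onset)) {
    stop("dci_onset_h must lie in (0, ", MONITORING_MAX_H, "] h")
  }

  unknown <- !(glucose$patient_id %in% patients$patient_id)
  if (any(unknown)) {
    stop(
      "glucose rows reference unknown patient_id: ",
      paste(unique(glucose$patient_id[unknown]), collapse = ", ")
    )
  }
  bad_val <- !is.finite(glucose$glucose_mgdl) | glucose$glucose_mgdl <= 0
  if (any(bad_val)) {
    stop(
      "non-numeric or non-positive glucose value at row(s) ",
      paste(head(which(bad_val), 5L), collapse = ", ")
    )
  }
  if (any(!is.finite(glucose$time_h) | glucose$time_h < 0)) {
    stop("measurement times must be finite and non-negative")
  }

  n_late <- sum(glucose$time_h > MONITORING_MAX_H)
  if (n_late > 0L) {
    message(
      "dropping ", n_late, " measurement(s) beyond ",
      MONITORING_MAX_H, " h monitoring horizon"
    )
    glucose <- glucose[glucose$time_h <= MONITORING_MAX_H, , drop = FALSE]
  }

  if (anyDuplicated(glucose[c("patient_id", "time_h")])) {
    stop("duplicate (patient_id, time_h) measurement")
  }

  glucose <- dplyr::arrange(glucose, .data$patient_id, .data$time_h)
  list(patients = patients, glucose = glucose)
}

#' Write a cohort to delimited text files
#'
#' Inverse of [read_cohort()].  Times are written to 0.01 h and glucose to
#' 0.1 mg/dL, the stated precision of the storage format.
#'
#' @param cohort list with `patients` and `glucose` tables.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  patients_path <- file.path(dir, "patients.csv")
  glucose_path <- file.path(dir, "glucose.csv")
  glucose <- cohort$glucose
  glucose$time_h <- round(glucose$time_h, 2)
  glucose$glucose_mgdl <- round(glucose$glucose_mgdl, 1)
  readr::write_csv(cohort$patients, patients_path, progress = FALSE)
  readr::write_csv(glucose, glucose_path, progress = FALSE)
  invisible(c(patients = patients_path, glucose = glucose_path))
}

#' Restrict one patient's trace to an analysis window
#'
#' For a DCI patient the trace splits at the onset time: `pre` holds
#' measurements strictly before onset, `post` those at or after onset
#' (half-open pre window, so a value taken exactly at onset counts as
#' post), and `total` their union.  No-DCI patients only have a `total`
#' window.
#'
#' @param trace tibble with columns `time_h`, `glucose_mgdl` for one
#'   patient (a `patient_id` column, if present, is carried through).
#' @param record one-row data frame from the patient table for the same
#'   patient.
#' @param label `"pre"`, `"post"` or `"total"`.
#' @return The trace restricted to the window, same columns.
#' @export
extract_window <- function(trace, record, label = c("total", "pre", "post")) {
  label <- match.arg(label)
  stopifnot(nrow(record) == 1L)
  if (label == "total") {
    return(trace)
  }
  if (record$group != "DCI") {
    stop("pre/post windows are only defined for DCI patients")
  }
  onset <- record$dci_onset_h
  if (label == "pre") {
    trace[trace$time_h < onset, , drop = FALSE]
  } else {
    trace[trace$time_h >= onset, , drop = FALSE]
  }
}

#' Windows applicable to a patient
#'
#' @param record one-row patient record.
#' @return `"total"` for no-DCI patients; `c("pre","post","total")` for DCI.
#' @export
applicable_windows <- function(record) {
  if (record$group == "DCI") c("pre", "post", "total") else "total"
}
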
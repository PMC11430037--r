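#' Mean blood glucose
#'
#' Arithmetic mean of all measurements in the window, ignoring their
#' spacing.
#'
#' @param glucose_mgdl numeric vector of glucose values (mg/dL).
#' @return MBG in mg/dL.
#' @export
mbg <- function(glucose_mgdl) {
  if (length(glucose_mgdl) < 1L) stop("mbg needs at least one measurement")
  mean(glucose_mgdl)
}

#' Time-weighted average glucose
#'
#' Area under the piecewise-linear glucose curve through the measurements
#' (trapezoidal rule) divided by the hours analysed, i.e. the span from
#' first to last measurement.  Robust to uneven sampling: repeated
#' measurements in a short interval do not dominate the average the way
#' they do for [mbg()].
#'
#' @param time_h measurement times in hours, strictly increasing.
#' @param glucose_mgdl matching glucose values (mg/dL).
#' @return TWAG in mg/dL, or `NA` when fewer than 2 measurements are
#'   available.
#' @export
twag <- function(time_h, glucose_mgdl) {
  stopifnot(length(time_h) == length(glucose_mgdl))
  if (length(time_h) < 2L) return(NA_real_)
  dt <- diff(time_h)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  span <- time_h[length(time_h)] - time_h[1L]
  area <- sum(dt * (head(glucose_mgdl, -1L) + tail(glucose_mgdl, -1L)) / 2)
  area / span
}

#' Coefficient of glycemic variation
#'
#' Sample standard deviation (n − 1 denominator) divided by the mean blood
#' glucose, as a percentage.  Scale-free: multiplying all values by a
#' constant leaves the CV unchanged.
#'
#' @inheritParams mbg
#' @return CV in percent, or `NA` with fewer than 2 measurements.
#' @export
glycemic_cv <- function(glucose_mgdl) {
  if (length(glucose_mgdl) < 2L) return(NA_real_)
  100 * sd(glucose_mgdl) / mean(glucose_mgdl)
}

#' Average absolute change by time difference
#'
#' Mean over consecutive measurement pairs of the absolute glucose change
#' divided by the elapsed time — a sampling-aware fluctuation index in
#' mg/dL per hour.
#'
#' @inheritParams twag
#' @return AACTD in mg/dL/h, or `NA` with fewer than 2 measurements.
#' @export
aactd <- function(time_h, glucose_mgdl) {
  stopifnot(length(time_h) == length(glucose_mgdl))
  if (length(time_h) < 2L) return(NA_real_)
  dt <- diff(time_h)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  mean(abs(diff(glucose_mgdl)) / dt)
}

#' Per-patient, per-window index panels
#'
#' Computes MBG, TWAG, CV, AACTD and the individual TUDR at the three
#' corridors for every applicable (patient, window) pair: the total
#' monitoring period for every patient, plus the pre-onset and post-onset
#' windows for DCI patients.  Windows with fewer than 2 measurements give
#' a row of missing index values; the dropped windows are listed in the
#' `"incomplete"` attribute of the result.
#'
#' @param cohort list with `patients` and `glucose` tables.
#' @param period_length TUDR period length in hours.
#' @param corridors upper corridor bounds in mg/dL.
#' @param low shared hypoglycemia bound in mg/dL.
#' @return A tibble with one row per (patient, window): identifiers,
#'   `n_measurements`, `span_h`, `mbg`, `twag`, `cv`, `aactd` and one
#'   `tudr<high>` column per corridor.
#' @export
compute_panels <- function(cohort, period_length = 6,
                           corridors = c(140, 160, 180),
                           low = CORRIDOR_LOW_MGDL) {
  patients <- cohort$patients
  glucose <- cohort$glucose
  rows <- list()
  incomplete <- list()
  for (i in seq_len(nrow(patients))) {
    record <- patients[i, ]
    trace <- glucose[glucose$patient_id == record$patient_id, , drop = FALSE]
    for (label in applicable_windows(record)) {
      win <- extract_window(trace, record, label)
      m <- nrow(win)
      row <- tibble::tibble(
        patient_id = record$patient_id,
        group = record$group,
        window = label,
        n_measurements = m,
        span_h = if (m > 0L) max(win$time_h) - min(win$time_h) else NA_real_
      )
      if (m >= 2L) {
        row$mbg <- mbg(win$glucose_mgdl)
        row$twag <- twag(win$time_h, win$glucose_mgdl)
        row$cv <- glycemic_cv(win$glucose_mgdl)
        row$aactd <- aactd(win$time_h, win$glucose_mgdl)
        for (high in corridors) {
          row[[paste0("tudr", high)]] <-
            individual_tudr(win$time_h, win$glucose_mgdl,
              high = high, low = low, period_length = period_length)
        }
      } else {
        row$mbg <- row$twag <- row$cv <- row$aactd <- NA_real_
        for (high in corridors) row[[paste0("tudr", high)]] <- NA_real_
        incomplete[[length(incomplete) + 1L]] <- tibble::tibble(
          patient_id = record$patient_id, window = label, n_measurements = m
        )
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  panels <- dplyr::bind_rows(rows)
  incomplete <- dplyr::bind_rows(incomplete)
  if (nrow(incomplete) > 0L) {
    message(
      nrow(incomplete),
      " window(s) with fewer than 2 measurements; indices set to NA"
    )
  }
  attr(panels, "incomplete") <- incomplete
  panels
}
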
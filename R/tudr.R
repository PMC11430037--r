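#' @noRd
#' Admission-anchored period index for each measurement time.
#'
#' Periods are half-open [kL, (k+1)L).  The grid is clipped at the last
#' measurement: a measurement falling exactly on the grid boundary that
#' closes the observed span is assigned to the final evaluated period, so
#' a 30-h trace on a 6-h grid occupies periods 0..4, not a sixth period of
#' zero width.
period_index_admission <- function(time_h, period_length,
                                   anchor = 0, eps = 1e-9) {
  t_rel <- time_h - anchor
  n_periods <- max(ceiling(max(t_rel) / period_length - eps), 1L)
  pmin(floor(t_rel / period_length + eps), n_periods - 1L)
}

#' Signed event-anchored period index (no period zero)
#'
#' Periods count away from the event: k = −1 is \[onset − L, onset), k = +1
#' is \[onset, onset + L), and so on.  A measurement exactly at onset falls
#' in k = +1, matching the half-open pre-window convention.
#'
#' @param time_h measurement times (hours since admission).
#' @param onset_h event time (hours since admission).
#' @param period_length period length L in hours.
#' @return Integer vector of signed period indices (never 0).
#' @export
period_index_event <- function(time_h, onset_h, period_length) {
  kk <- floor((time_h - onset_h) / period_length + 1e-9)
  as.integer(ifelse(kk >= 0, kk + 1L, kk))
}

#' Fraction of grid periods covered by at least one measurement
#'
#' Over the admission-anchored grid of the given period length, the
#' fraction of periods between the patient's first and last measurement
#' (inclusive) that contain at least one measurement.
#'
#' @param time_h measurement times in hours, sorted increasing.
#' @param period_length period length in hours.
#' @return Proportion in \[0, 1\].
#' @export
coverage_fraction <- function(time_h, period_length) {
  if (length(time_h) < 1L) stop("coverage_fraction needs measurements")
  k <- period_index_admission(time_h, period_length)
  (length(unique(k))) / (max(k) - min(k) + 1L)
}

#' Apply the period-length selection rule to per-candidate coverages
#'
#' Returns the shortest candidate whose median per-patient coverage meets
#' the threshold.
#'
#' @param medians numeric vector of median coverages, one per candidate,
#'   in candidate order.
#' @param candidates candidate period lengths in hours.
#' @param threshold required median coverage.
#' @return The selected period length in hours.
#' @export
select_period_from_coverage <- function(medians, candidates = c(1, 3, 6, 12),
                                        threshold = 0.95) {
  stopifnot(length(medians) == length(candidates))
  ord <- order(candidates)
  candidates <- candidates[ord]
  medians <- medians[ord]
  ok <- which(medians >= threshold)
  if (length(ok) == 0L) {
    stop(
      "no candidate period length reaches median coverage ", threshold,
      " (medians: ",
      paste(sprintf("%gh: %.3f", candidates, medians), collapse = ", "), ")"
    )
  }
  candidates[ok[1L]]
}

#' Select the TUDR period length from cohort measurement coverage
#'
#' For each candidate period length, computes every patient's
#' [coverage_fraction()] over the total monitoring trace and takes the
#' cohort median; the shortest candidate whose median meets the threshold
#' is selected.
#'
#' @param cohort list with `patients` and `glucose` tables.
#' @param candidates candidate period lengths in hours.
#' @param threshold required median coverage (default 0.95).
#' @return A list with `period_h` (selected length) and `medians`
#'   (named numeric vector of per-candidate median coverages).
#' @export
select_period_length <- function(cohort, candidates = c(1, 3, 6, 12),
                                 threshold = 0.95) {
  glucose <- cohort$glucose
  if (nrow(glucose) == 0L) stop("empty glucose table")
  by_patient <- split(glucose$time_h, glucose$patient_id)
  medians <- vapply(candidates, function(L) {
    median(vapply(by_patient, coverage_fraction, numeric(1),
      period_length = L))
  }, numeric(1))
  names(medians) <- paste0(candidates, "h")
  list(
    period_h = select_period_from_coverage(medians, candidates, threshold),
    medians = medians
  )
}

#' Individual time-unified dysglycemic rate
#'
#' Partitions the admission-anchored timeline into fixed-length periods
#' and reports the fraction of periods containing at least one
#' measurement outside the glycemic corridor, among periods containing at
#' least one measurement.  Periods without any measurement are excluded
#' from numerator and denominator (`count_empty = FALSE`, the default);
#' `count_empty = TRUE` instead counts them in the denominator as
#' normoglycemic.
#'
#' @param time_h measurement times in hours, sorted increasing.
#' @param glucose_mgdl matching glucose values.
#' @param high upper corridor bound in mg/dL (140, 160 or 180 in the
#'   standard panels).
#' @param low lower corridor bound in mg/dL (default 70).
#' @param period_length period length in hours.
#' @param count_empty whether empty periods enter the denominator.
#' @return Proportion of dysglycemic periods in \[0, 1\], or `NA` when no
#'   period contains a measurement.
#' @export
individual_tudr <- function(time_h, glucose_mgdl, high,
                            low = CORRIDOR_LOW_MGDL, period_length = 6,
                            count_empty = FALSE) {
  stopifnot(length(time_h) == length(glucose_mgdl), high > low)
  if (length(time_h) == 0L) return(NA_real_)
  k <- period_index_admission(time_h, period_length)
  out <- glucose_mgdl < low | glucose_mgdl > high
  n_dys <- length(unique(k[out]))
  n_total <- if (count_empty) {
    max(k) - min(k) + 1L
  } else {
    length(unique(k))
  }
  n_dys / n_total
}

#' Cumulative event-aligned dysglycemia and TWAG curves
#'
#' Aligns all DCI patients at their own onset (time zero) and, for every
#' signed 6-h (or other) period within the horizon, reports how many
#' patients have any measurement in the period (`n_present`), how many of
#' those have at least one value outside the corridor
#' (`n_dysglycemic`), their ratio (`rate`, the cumulative TUDR), and the
#' distribution of within-period per-patient TWAGs.
#'
#' @param cohort list with `patients` and `glucose`; only DCI patients
#'   (with an onset time) are used.
#' @param high upper corridor bound in mg/dL.
#' @param low lower corridor bound in mg/dL.
#' @param period_length period length in hours.
#' @param horizon extent of the curve on each side of onset, in hours;
#'   must be a multiple of `period_length`.
#' @return A tibble with one row per signed period `k` in
#'   \[−horizon/L, −1\] and \[+1, +horizon/L\]: `period` (k),
#'   `start_h`/`end_h` relative to onset, `n_present`, `n_dysglycemic`,
#'   `rate`, `twag_median` and a `twag_values` list column of the
#'   per-patient period TWAGs (patients with ≥ 2 measurements in the
#'   period).
#' @export
cumulative_curves <- function(cohort, high, low = CORRIDOR_LOW_MGDL,
                              period_length = 6, horizon = 168) {
  if (abs(horizon / period_length - round(horizon / period_length)) > 1e-9) {
    stop("horizon must be a multiple of period_length")
  }
  patients <- cohort$patients[cohort$patients$group == "DCI", , drop = FALSE]
  if (nrow(patients) == 0L) stop("no DCI patients in cohort")
  if (any(!is.finite(patients$dci_onset_h))) {
    stop("every DCI patient needs an onset time")
  }
  glucose <- cohort$glucose[
    cohort$glucose$patient_id %in% patients$patient_id, , drop = FALSE]
  glucose <- dplyr::left_join(
    glucose, patients[c("patient_id", "dci_onset_h")], by = "patient_id"
  )
  glucose$period <- period_index_event(
    glucose$time_h, glucose$dci_onset_h, period_length
  )

  k_max <- as.integer(round(horizon / period_length))
  k_grid <- c(seq.int(-k_max, -1L), seq.int(1L, k_max))

  per_patient <- glucose |>
    dplyr::filter(abs(.data$period) <= k_max) |>
    dplyr::group_by(.data$patient_id, .data$period) |>
    dplyr::summarise(
      any_out = any(.data$glucose_mgdl < low | .data$glucose_mgdl > high),
      twag = if (dplyr::n() >= 2L) {
        twag(.data$time_h, .data$glucose_mgdl)
      } else {
        NA_real_
      },
      .groups = "drop"
    )

  out <- lapply(k_grid, function(k) {
    rows <- per_patient[per_patient$period == k, , drop = FALSE]
    twags <- rows$twag[!is.na(rows$twag)]
    tibble::tibble(
      period = k,
      start_h = ifelse(k < 0, k * period_length, (k - 1) * period_length),
      end_h = ifelse(k < 0, (k + 1) * period_length, k * period_length),
      n_present = nrow(rows),
      n_dysglycemic = sum(rows$any_out),
      rate = if (nrow(rows) > 0L) sum(rows$any_out) / nrow(rows)
             else NA_real_,
      twag_median = if (length(twags) > 0L) median(twags) else NA_real_,
      twag_values = list(twags)
    )
  })
  dplyr::bind_rows(out)
}
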
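#' Run the full glycemic analysis cascade on a cohort
#'
#' Chains the pipeline end to end: TUDR period-length selection from
#' measurement coverage, per-patient index panels, non-parametric group
#' comparisons of every index (no-DCI vs the DCI pre/post/total windows,
#' and paired pre-vs-post within the DCI group), correlation-screened
#' univariate/multivariable logistic regression of DCI on the
#' total-window indices plus admission covariates, cumulative
#' event-aligned curves, and interrupted time-series analysis of the
#' per-period median TWAG and of the cumulative TUDR rate at each
#' corridor.
#'
#' @param cohort list with `patients` and `glucose` tables.
#' @param period_length TUDR period length in hours, or `NULL` to select
#'   it from coverage (candidates 1/3/6/12 h, 95% median threshold).
#' @param corridors upper corridor bounds in mg/dL.
#' @param horizon event-aligned curve extent on each side of onset (h).
#' @return A list: `period_h`, `coverage_medians`, `panels`,
#'   `comparisons`, `screening`, `regression`, `cumulative` (per
#'   corridor), `its`.
#' @export
analyze_cohort <- function(cohort, period_length = NULL,
                           corridors = c(140, 160, 180), horizon = 168) {
  coverage_medians <- NULL
  if (is.null(period_length)) {
    sel <- select_period_length(cohort)
    period_length <- sel$period_h
    coverage_medians <- sel$medians
  }
  panels <- compute_panels(cohort, period_length = period_length,
    corridors = corridors)

  index_cols <- c("mbg", "twag", "cv", "aactd",
    paste0("tudr", corridors))
  nodci <- panels[panels$group == "noDCI" & panels$window == "total", ]
  comparisons <- list()
  for (v in index_cols) {
    for (w in c("pre", "post", "total")) {
      dci <- panels[panels$group == "DCI" & panels$window == w, ]
      res <- compare_unpaired(nodci[[v]][is.finite(nodci[[v]])],
        dci[[v]][is.finite(dci[[v]])], family = "rank")
      res$variable <- v
      res$comparison <- paste0("noDCI_vs_", w)
      comparisons[[length(comparisons) + 1L]] <- res
    }
    pre <- panels[panels$group == "DCI" & panels$window == "pre", ]
    post <- panels[panels$group == "DCI" & panels$window == "post", ]
    paired <- dplyr::inner_join(
      pre[c("patient_id", v)], post[c("patient_id", v)],
      by = "patient_id", suffix = c("_pre", "_post")
    )
    res <- compare_paired(paired[[paste0(v, "_pre")]],
      paired[[paste0(v, "_post")]])
    res$variable <- v
    res$comparison <- "pre_vs_post"
    comparisons[[length(comparisons) + 1L]] <- res
  }
  comparisons <- dplyr::bind_rows(comparisons)

  # regression table: total-window indices plus admission covariates
  total <- panels[panels$window == "total", ]
  features <- dplyr::left_join(
    total[c("patient_id", "group", index_cols)],
    cohort$patients[c("patient_id", "age", "sex", "mfisher",
      "hunt_hess", "saps2")],
    by = "patient_id"
  )
  features$dci <- as.integer(features$group == "DCI")
  features$sex_female <- as.integer(features$sex == "female")
  predictors <- c(index_cols, "age", "sex_female", "mfisher",
    "hunt_hess", "saps2")
  screening <- screen_predictors(features, "dci", predictors)
  regression <- logistic_cascade(features, "dci", screening$retained)

  cumulative <- lapply(setNames(corridors, paste0("tudr", corridors)),
    function(high) {
      cumulative_curves(cohort, high = high,
        period_length = period_length, horizon = horizon)
    })

  its <- list()
  cc1 <- cumulative[[1L]]
  res <- interrupted_time_series(cc1$period, cc1$twag_median)
  res$series <- "twag"
  its[[1L]] <- res
  for (nm in names(cumulative)) {
    cc <- cumulative[[nm]]
    res <- interrupted_time_series(cc$period, cc$rate)
    res$series <- nm
    its[[length(its) + 1L]] <- res
  }
  its <- dplyr::bind_rows(its)

  list(
    period_h = period_length, coverage_medians = coverage_medians,
    panels = panels, comparisons = comparisons, screening = screening,
    regression = regression, cumulative = cumulative, its = its
  )
}
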
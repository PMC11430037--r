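#' Configuration for the synthetic cohort generator
#'
#' Defaults describe an aneurysmal-SAH ICU cohort monitored for up to 14
#' days: 46.4% of patients develop delayed cerebral ischemia (DCI) with
#' onset uniform between day 3 and day 14; glucose is sampled irregularly
#' with mean ± SD inter-measurement intervals of 4.0 ± 1.6 h (no-DCI) and
#' 2.8 ± 0.8 h (DCI); glucose levels sit near 125.6 mg/dL (no-DCI),
#' 130.7 mg/dL before DCI onset and 149.2 mg/dL after, with a
#' coefficient of variation near 18% and lag-1 autocorrelated noise.
#'
#' @param n_patients number of patients.
#' @param dci_fraction proportion of patients labelled DCI.
#' @param interval_mean_nodci,interval_sd_nodci inter-measurement interval
#'   mean and SD (hours) for no-DCI patients.
#' @param interval_mean_dci,interval_sd_dci same for DCI patients.
#' @param setpoint_nodci,setpoint_pre,setpoint_post glucose process means
#'   (mg/dL): constant for no-DCI; pre/post levels switching at onset for
#'   DCI patients.
#' @param cv_target coefficient of variation of the multiplicative noise.
#' @param onset_min,onset_max bounds (hours) of the uniform DCI-onset
#'   distribution.
#' @param monitoring_max monitoring horizon in hours.
#' @param ar_coefficient lag-1 autocorrelation of the noise process,
#'   in \[0, 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_patients = 151,
                             dci_fraction = 0.464,
                             interval_mean_nodci = 4.0,
                             interval_sd_nodci = 1.6,
                             interval_mean_dci = 2.8,
                             interval_sd_dci = 0.8,
                             setpoint_nodci = 125.6,
                             setpoint_pre = 130.7,
                             setpoint_post = 149.2,
                             cv_target = 0.18,
                             onset_min = 72,
                             onset_max = 336,
                             monitoring_max = 336,
                             ar_coefficient = 0.5,
                             seed = NULL) {
  config <- list(
    n_patients = n_patients, dci_fraction = dci_fraction,
    interval_mean_nodci = interval_mean_nodci,
    interval_sd_nodci = interval_sd_nodci,
    interval_mean_dci = interval_mean_dci,
    interval_sd_dci = interval_sd_dci,
    setpoint_nodci = setpoint_nodci, setpoint_pre = setpoint_pre,
    setpoint_post = setpoint_post, cv_target = cv_target,
    onset_min = onset_min, onset_max = onset_max,
    monitoring_max = monitoring_max, ar_coefficient = ar_coefficient,
    seed = seed
  )
  stopifnot(
    n_patients >= 4,
    dci_fraction > 0, dci_fraction < 1,
    interval_mean_nodci > 0, interval_mean_dci > 0,
    cv_target >= 0,
    onset_min < onset_max, onset_max <= monitoring_max,
    ar_coefficient >= 0, ar_coefficient < 1
  )
  structure(config, class = "generator_config")
}

# intervals from a normal truncated below at `lower`, by inverse CDF
rtruncnorm_lower <- function(n, mean, sd, lower = 0.25) {
  p_lo <- pnorm((lower - mean) / sd)
  mean + sd * qnorm(p_lo + runif(n) * (1 - p_lo))
}

# stationary standard-normal AR(1) path
ar1_path <- function(n, phi) {
  z <- rnorm(n)
  if (phi > 0 && n > 1L) {
    innov <- z * sqrt(1 - phi^2)
    innov[1L] <- z[1L]
    z <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  }
  z
}

#' Generate a synthetic aSAH ICU cohort with known ground truth
#'
#' Draws group labels, DCI-onset times, covariates, irregular measurement
#' grids (truncated-normal inter-measurement intervals, lower bound
#' 0.25 h) and glucose values.  Values follow
#' `setpoint(t) * (1 + cv_target * z_t)` where the setpoint is constant
#' for no-DCI patients and steps from the pre to the post level at DCI
#' onset, and `z_t` is a stationary lag-1 autoregressive standard-normal
#' sequence.  Values are floored at 40 mg/dL.  Covariates (age, sex,
#' mFisher, Hunt & Hess, SAPS II) are drawn with group-dependent
#' distributions and an age–SAPS II correlation near 0.5.
#'
#' @param config a [generator_config()].
#' @return A list with `patients`, `glucose` (as in [read_cohort()]) and
#'   `truth`, a per-patient tibble of generating parameters with the
#'   config attached as attribute `"config"`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_patients < 4) {
    stop("need at least 4 patients to form both groups")
  }
  if (!is.null(config$seed)) {
    old_seed <- if (exists(".Random.seed", envir = .GlobalEnv)) {
      get(".Random.seed", envir = .GlobalEnv)
    }
    on.exit(
      if (!is.null(old_seed)) {
        assign(".Random.seed", old_seed, envir = .GlobalEnv)
      },
      add = TRUE
    )
    set.seed(config$seed)
  }

  n <- config$n_patients
  n_dci <- round(n * config$dci_fraction)
  n_dci <- min(max(n_dci, 2L), n - 2L)
  group <- c(rep("DCI", n_dci), rep("noDCI", n - n_dci))
  patient_id <- sprintf("P%04d", seq_len(n))
  is_dci <- group == "DCI"

  onset <- rep(NA_real_, n)
  onset[is_dci] <- runif(n_dci, config$onset_min, config$onset_max)

  # covariates: younger age, higher mFisher/SAPS II in the DCI group;
  # age and SAPS II share a latent factor giving r near 0.5
  age_mean <- ifelse(is_dci, 52.9, 57.2)
  age_sd <- ifelse(is_dci, 11.8, 12.6)
  age_z <- rnorm(n)
  age <- pmin(pmax(round(age_mean + age_sd * age_z), 18), 95)
  sex <- ifelse(runif(n) < 0.669, "female", "male")
  mf_p34 <- ifelse(is_dci, 0.70, 0.37)
  mfisher <- ifelse(
    runif(n) < mf_p34,
    sample(3:4, n, replace = TRUE),
    sample(1:2, n, replace = TRUE)
  )
  hh_p45 <- ifelse(is_dci, 0.357, 0.259)
  hunt_hess <- ifelse(
    runif(n) < hh_p45,
    sample(4:5, n, replace = TRUE),
    sample(1:3, n, replace = TRUE)
  )
  saps_mean <- ifelse(is_dci, 39.1, 36.0)
  saps2 <- pmax(round(saps_mean + 9 * (0.5 * age_z +
    sqrt(0.75) * rnorm(n))), 6L)

  patients <- tibble::tibble(
    patient_id = patient_id, group = group, dci_onset_h = onset,
    age = as.numeric(age), sex = sex, mfisher = as.integer(mfisher),
    hunt_hess = as.integer(hunt_hess), saps2 = as.integer(saps2)
  )

  int_mean <- ifelse(is_dci, config$interval_mean_dci,
    config$interval_mean_nodci)
  int_sd <- ifelse(is_dci, config$interval_sd_dci, config$interval_sd_nodci)

  traces <- vector("list", n)
  for (i in seq_len(n)) {
    n_draw <- ceiling(config$monitoring_max / int_mean[i] * 1.5) + 20L
    times <- c(0, cumsum(rtruncnorm_lower(n_draw, int_mean[i], int_sd[i])))
    times <- times[times <= config$monitoring_max]
    m <- length(times)
    setpoint <- if (is_dci[i]) {
      ifelse(times < onset[i], config$setpoint_pre, config$setpoint_post)
    } else {
      rep(config$setpoint_nodci, m)
    }
    value <- setpoint * (1 + config$cv_target *
      ar1_path(m, config$ar_coefficient))
    traces[[i]] <- tibble::tibble(
      patient_id = patient_id[i],
      time_h = times,
      glucose_mgdl = pmax(value, 40)
    )
  }
  glucose <- dplyr::bind_rows(traces)

  truth <- tibble::tibble(
    patient_id = patient_id, group = group, dci_onset_h = onset,
    setpoint_pre = ifelse(is_dci, config$setpoint_pre,
      config$setpoint_nodci),
    setpoint_post = ifelse(is_dci, config$setpoint_post,
      config$setpoint_nodci),
    interval_mean = int_mean, interval_sd = int_sd,
    cv_target = config$cv_target
  )
  attr(truth, "config") <- config

  list(patients = patients, glucose = glucose, truth = truth)
}

#' Build a glucose trace verbatim from (time, value) pairs
#'
#' Convenience constructor for worked examples and test fixtures.
#'
#' @param time_h numeric vector of strictly increasing times (hours since
#'   ICU admission).
#' @param glucose_mgdl matching glucose values (mg/dL).
#' @param patient_id identifier attached to every row.
#' @return A tibble with columns `patient_id`, `time_h`, `glucose_mgdl`.
#' @export
make_fixture_trace <- function(time_h, glucose_mgdl, patient_id = "FIX") {
  stopifnot(length(time_h) == length(glucose_mgdl))
  if (length(time_h) > 1L && any(diff(time_h) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (any(time_h < 0) || any(glucose_mgdl <= 0)) {
    stop("times must be non-negative and glucose positive")
  }
  tibble::tibble(
    patient_id = patient_id,
    time_h = as.numeric(time_h),
    glucose_mgdl = as.numeric(glucose_mgdl)
  )
}
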
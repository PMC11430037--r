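#' Two-group comparison of a continuous variable
#'
#' Families: `"rank"` (Mann–Whitney U, used for the glycemic indices),
#' `"t"` (unpaired Welch t-test, used for baseline characteristics) and
#' `"bootstrap_t"` (percentile-t resampling of the Welch statistic under
#' the null of equal means, for skewed variables such as BMI).  All tests
#' are two-sided.
#'
#' @param values_a,values_b numeric vectors, one per group (≥ 2 each).
#' @param family test family.
#' @param n_boot bootstrap replicates for `family = "bootstrap_t"`.
#' @param seed optional seed for the bootstrap.
#' @return One-row tibble: `test`, `statistic`, `p_value`, group sizes,
#'   medians, IQR bounds, means, SDs and a `degenerate` flag (set when
#'   every value in both groups is identical, in which case p = 1).
#' @export
compare_unpaired <- function(values_a, values_b,
                             family = c("rank", "t", "bootstrap_t"),
                             n_boot = 10000, seed = NULL) {
  family <- match.arg(family)
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("need at least 2 values per group")
  }
  degenerate <- length(unique(c(values_a, values_b))) == 1L
  if (degenerate) {
    stat <- NA_real_
    p <- 1
    test_name <- family
  } else if (family == "rank") {
    fit <- suppressWarnings(wilcox.test(values_a, values_b))
    stat <- unname(fit$statistic)
    p <- fit$p.value
    test_name <- "Mann-Whitney U"
  } else if (family == "t") {
    fit <- t.test(values_a, values_b)
    stat <- unname(fit$statistic)
    p <- fit$p.value
    test_name <- "Welch t"
  } else {
    if (!is.null(seed)) set.seed(seed)
    stat <- unname(t.test(values_a, values_b)$statistic)
    # resample groups centred at their own means (null of equal means)
    ca <- values_a - mean(values_a)
    cb <- values_b - mean(values_b)
    t_null <- vapply(seq_len(n_boot), function(i) {
      ra <- sample(ca, replace = TRUE)
      rb <- sample(cb, replace = TRUE)
      if (sd(ra) == 0 && sd(rb) == 0) return(0)
      unname(t.test(ra, rb)$statistic)
    }, numeric(1))
    p <- (1 + sum(abs(t_null) >= abs(stat))) / (1 + n_boot)
    test_name <- "bootstrap t"
  }
  tibble::tibble(
    test = test_name, statistic = stat, p_value = p,
    n_a = length(values_a), n_b = length(values_b),
    median_a = median(values_a), median_b = median(values_b),
    q1_a = unname(quantile(values_a, 0.25)),
    q3_a = unname(quantile(values_a, 0.75)),
    q1_b = unname(quantile(values_b, 0.25)),
    q3_b = unname(quantile(values_b, 0.75)),
    mean_a = mean(values_a), mean_b = mean(values_b),
    sd_a = sd(values_a), sd_b = sd(values_b),
    degenerate = degenerate
  )
}

#' Paired pre/post comparison (Wilcoxon signed rank)
#'
#' Two-sided matched-pairs signed-rank test; pairs with a missing member
#' are dropped.  When every difference is zero the result is flagged
#' degenerate with p = 1.
#'
#' @param pre_values,post_values paired numeric vectors of equal length.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n_pairs`,
#'   medians and a `degenerate` flag.
#' @export
compare_paired <- function(pre_values, post_values) {
  stopifnot(length(pre_values) == length(post_values))
  ok <- is.finite(pre_values) & is.finite(post_values)
  pre_values <- pre_values[ok]
  post_values <- post_values[ok]
  if (length(pre_values) < 1L) stop("no complete pairs")
  d <- post_values - pre_values
  if (all(d == 0)) {
    return(tibble::tibble(
      test = "Wilcoxon signed rank", statistic = NA_real_, p_value = 1,
      n_pairs = length(d),
      median_pre = median(pre_values), median_post = median(post_values),
      degenerate = TRUE
    ))
  }
  dnz <- d[d != 0]
  r <- rank(abs(dnz))
  v_obs <- sum(r[dnz > 0])
  if (length(dnz) <= 15L && anyDuplicated(r)) {
    # tied ranks: base wilcox.test would fall back to a normal
    # approximation; enumerate the 2^n sign flips exactly instead
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(dnz))))
    v_all <- as.numeric(signs %*% r)
    p <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  } else {
    p <- suppressWarnings(
      wilcox.test(post_values, pre_values, paired = TRUE)$p.value
    )
  }
  tibble::tibble(
    test = "Wilcoxon signed rank",
    statistic = v_obs, p_value = p,
    n_pairs = length(d),
    median_pre = median(pre_values), median_post = median(post_values),
    degenerate = FALSE
  )
}

#' Fisher's exact test on a 2×2 table
#'
#' Two-sided exact test of association for binary variables.  A table
#' with an empty margin carries no information and returns p = 1 with a
#' degenerate flag.
#'
#' @param table 2×2 matrix of non-negative integer counts.
#' @return One-row tibble: `test`, `odds_ratio` (conditional MLE),
#'   `p_value`, `degenerate`.
#' @export
fisher_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0),
    all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(tibble::tibble(
      test = "Fisher exact", odds_ratio = NA_real_, p_value = 1,
      degenerate = TRUE
    ))
  }
  fit <- fisher.test(table)
  tibble::tibble(
    test = "Fisher exact", odds_ratio = unname(fit$estimate),
    p_value = fit$p.value, degenerate = FALSE
  )
}

#' Screen correlated predictors before logistic regression
#'
#' Computes pairwise Pearson correlations among candidate predictors on
#' complete cases; predictors linked by a correlation at or above the
#' threshold are grouped (transitive closure, so a chain A–B, B–C forms
#' one group) and only the group member with the smallest univariate
#' logistic-regression p-value against the outcome is retained.
#' Constant predictors are excluded up front.
#'
#' @param data data frame holding the outcome and predictor columns.
#' @param outcome name of the binary outcome column (0/1, logical, or a
#'   two-level factor).
#' @param predictors predictor column names; defaults to every numeric
#'   column except the outcome.
#' @param r_threshold Pearson correlation at or above which two
#'   predictors are considered collinear (default 0.50).
#' @return A list: `retained` (character), `dropped` (character),
#'   `log` (tibble of screening decisions), `correlations` (matrix),
#'   `univariate_p` (named vector).
#' @export
screen_predictors <- function(data, outcome, predictors = NULL,
                              r_threshold = 0.50) {
  data <- as.data.frame(data)
  stopifnot(outcome %in% names(data))
  if (is.null(predictors)) {
    predictors <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))], outcome
    )
  }
  y <- outcome_as_binary(data[[outcome]])
  keep <- complete.cases(data[predictors]) & !is.na(y)
  x <- data[keep, predictors, drop = FALSE]
  y <- y[keep]

  log <- list()
  constant <- names(x)[vapply(x, function(v) sd(v) == 0, logical(1))]
  for (v in constant) {
    log[[length(log) + 1L]] <- tibble::tibble(
      action = "exclude_constant", predictor = v,
      detail = "constant predictor carries no information"
    )
  }
  predictors <- setdiff(predictors, constant)
  x <- x[predictors]
  if (length(predictors) == 0L) stop("no usable predictors")

  p_uni <- vapply(predictors, function(v) {
    summary(glm(y ~ x[[v]], family = binomial()))$coefficients[2, 4]
  }, numeric(1))

  r_mat <- cor(x, method = "pearson")
  n_pred <- length(predictors)
  # transitive closure over pairs with r >= threshold (union-find)
  parent <- seq_len(n_pred)
  find_root <- function(k) {
    while (parent[k] != k) k <- parent[k]
    k
  }
  for (i in seq_len(n_pred - 1L)) {
    for (j in seq.int(i + 1L, n_pred)) {
      if (r_mat[i, j] >= r_threshold) {
        ri <- find_root(i)
        rj <- find_root(j)
        if (ri != rj) parent[rj] <- ri
        log[[length(log) + 1L]] <- tibble::tibble(
          action = "correlated_pair",
          predictor = paste(predictors[i], predictors[j], sep = "~"),
          detail = sprintf("r = %.3f >= %.2f", r_mat[i, j], r_threshold)
        )
      }
    }
  }
  roots <- vapply(seq_len(n_pred), find_root, integer(1))
  retained <- character(0)
  for (r in unique(roots)) {
    members <- predictors[roots == r]
    best <- members[which.min(p_uni[members])]
    retained <- c(retained, best)
    if (length(members) > 1L) {
      log[[length(log) + 1L]] <- tibble::tibble(
        action = "retain_lowest_p",
        predictor = best,
        detail = sprintf(
          "kept over {%s}; univariate p = %.4g",
          paste(setdiff(members, best), collapse = ", "), p_uni[best]
        )
      )
    }
  }
  retained <- predictors[predictors %in% retained] # original column order
  list(
    retained = retained,
    dropped = c(constant, setdiff(predictors, retained)),
    log = if (length(log) > 0L) dplyr::bind_rows(log) else tibble::tibble(
      action = character(0), predictor = character(0), detail = character(0)
    ),
    correlations = r_mat,
    univariate_p = p_uni
  )
}

outcome_as_binary <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.factor(y)) {
    stopifnot(nlevels(y) == 2L)
    return(as.integer(y) - 1L)
  }
  stopifnot(all(y %in% c(0, 1) | is.na(y)))
  as.integer(y)
}

#' Univariate then multivariable logistic regression
#'
#' Fits one logistic model per predictor, reporting the per-unit odds
#' ratio with a Wald 95% confidence interval; predictors with univariate
#' p below `p_enter` are then fitted jointly in one multivariable model.
#' Predictors whose univariate fit fails to converge or shows separation
#' (explosive standard errors) are flagged and kept out of the joint
#' model.
#'
#' @param data data frame with outcome and predictors.
#' @param outcome name of the binary outcome column.
#' @param predictors predictor column names (typically the `retained` set
#'   from [screen_predictors()]).
#' @param p_enter univariate p-value cutoff for entering the joint model.
#' @return A list with tibbles `univariate` and `multivariable`
#'   (`term`, `estimate` = log-odds, `or`, `ci_low`, `ci_high`,
#'   `p_value`, `flag`) and `entered`, the predictors in the joint model.
#' @export
logistic_cascade <- function(data, outcome, predictors,
                             p_enter = 0.05) {
  data <- as.data.frame(data)
  y <- outcome_as_binary(data[[outcome]])
  keep <- complete.cases(data[predictors]) & !is.na(y)
  data <- data[keep, , drop = FALSE]
  y <- y[keep]

  one_row <- function(fit, term, flag = NA_character_) {
    s <- summary(fit)$coefficients
    est <- s[term, 1]
    se <- s[term, 2]
    if (!fit$converged || se > 100) {
      flag <- if (is.na(flag)) "nonconvergence_or_separation" else flag
    }
    tibble::tibble(
      term = term, estimate = est, or = exp(est),
      ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
      p_value = s[term, 4], flag = flag
    )
  }

  univariate <- dplyr::bind_rows(lapply(predictors, function(v) {
    fit <- suppressWarnings(
      glm(y ~ x, data = data.frame(y = y, x = data[[v]]),
        family = binomial())
    )
    row <- one_row(fit, "x")
    row$term <- v
    row
  }))

  entered <- univariate$term[
    univariate$p_value < p_enter & is.na(univariate$flag)]
  multivariable <- tibble::tibble(
    term = character(0), estimate = numeric(0), or = numeric(0),
    ci_low = numeric(0), ci_high = numeric(0), p_value = numeric(0),
    flag = character(0)
  )
  if (length(entered) > 0L) {
    df <- data.frame(y = y, data[entered])
    fit <- suppressWarnings(glm(
      stats::reformulate(entered, response = "y"),
      data = df, family = binomial()
    ))
    multivariable <- dplyr::bind_rows(lapply(entered, one_row, fit = fit))
  }
  list(univariate = univariate, multivariable = multivariable,
    entered = entered)
}

#' Interrupted time-series analysis of an event-aligned series
#'
#' Segmented ordinary-least-squares regression of a per-period series on
#' the signed period index k (negative before, positive after the event,
#' no period zero):
#' `value ~ b0 + b1*k + b2*step + b3*(k - k_plus)*step` with
#' `step = 1(k > 0)` and `k_plus` the first post-event period.  `b2` is
#' the level change at the event, `b1` the pre-event slope and
#' `b1 + b3` the post-event slope (per period).
#'
#' @param period signed period indices.
#' @param value series values (e.g. per-period median TWAG or cumulative
#'   TUDR rate).
#' @return One-row tibble: `level_change`, `level_change_p`,
#'   `pre_slope`, `pre_slope_p`, `post_slope`, `post_slope_p`, `sigma`,
#'   `n_pre`, `n_post`.
#' @export
interrupted_time_series <- function(period, value) {
  ok <- is.finite(period) & is.finite(value)
  period <- period[ok]
  value <- value[ok]
  stopifnot(all(period != 0))
  n_pre <- sum(period < 0)
  n_post <- sum(period > 0)
  if (n_pre < 3L || n_post < 3L) {
    stop("need at least 3 points in each segment")
  }
  step <- as.numeric(period > 0)
  k_plus <- min(period[period > 0])
  post_time <- (period - k_plus) * step
  fit <- lm(value ~ period + step + post_time)
  s <- summary(fit)$coefficients
  # post slope is a linear combination b1 + b3
  cvec <- c(0, 1, 0, 1)
  post_slope <- sum(cvec * coef(fit))
  post_se <- sqrt(drop(t(cvec) %*% vcov(fit) %*% cvec))
  df_res <- fit$df.residual
  post_p <- if (post_se > 0) {
    2 * pt(abs(post_slope / post_se), df_res, lower.tail = FALSE)
  } else {
    NaN
  }
  tibble::tibble(
    level_change = unname(coef(fit)["step"]),
    level_change_p = s["step", 4],
    pre_slope = unname(coef(fit)["period"]),
    pre_slope_p = s["period", 4],
    post_slope = post_slope,
    post_slope_p = post_p,
    sigma = summary(fit)$sigma,
    n_pre = n_pre, n_post = n_post
  )
}
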
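test_that("rank comparison handles identity, separation and monotone transforms", {
  a <- c(1, 2, 3)
  res <- compare_unpaired(a, a, family = "rank")
  expect_equal(res$p_value, 1)
  # fully separated tiny groups attain the minimal exact p = 2/20
  res <- compare_unpaired(c(1, 2, 3), c(10, 11, 12), family = "rank")
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 0.1)
  # rank tests ignore strictly monotone transforms
  set.seed(51)
  x <- rnorm(12)
  y <- rnorm(10, 0.8)
  expect_equal(
    compare_unpaired(x, y, family = "rank")$p_value,
    compare_unpaired(exp(x), exp(y), family = "rank")$p_value
  )
  # degenerate: both groups a single repeated value
  res <- compare_unpaired(rep(5, 4), rep(5, 6), family = "rank")
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("unpaired tests match enumeration oracles for small samples", {
  set.seed(61)
  for (i in 1:15) {
    a <- round(rnorm(sample(3:6, 1), 0, 10), 3)
    b <- round(rnorm(sample(3:6, 1), 3, 10), 3)
    expect_equal(
      compare_unpaired(a, b, family = "rank")$p_value,
      oracle_rank_p(a, b),
      tolerance = 1e-12
    )
  }
})

test_that("paired signed-rank test: ties, exact floor, and oracle agreement", {
  pre <- c(3, 5, 1, 9)
  expect_true(compare_paired(pre, pre)$degenerate)
  # uniform shift of 8 pairs attains the exact two-sided floor 2/2^8
  pre8 <- rnorm(8)
  res <- compare_paired(pre8, pre8 + 10)
  expect_equal(res$p_value, 2 / 2^8)
  set.seed(71)
  for (i in 1:15) {
    n <- sample(5:10, 1)
    p0 <- round(rnorm(n, 0, 5), 3)
    p1 <- round(p0 + rnorm(n, 1, 5), 3)
    expect_equal(
      compare_paired(p0, p1)$p_value,
      oracle_signed_rank_p(p0, p1),
      tolerance = 1e-12
    )
  }
})

test_that("paired comparison detects the pre-to-post glucose shift in synthetic DCI patients", {
  co <- generate_cohort(generator_config(n_patients = 120, seed = 81))
  panels <- compute_panels(co)
  pre <- panels[panels$window == "pre", ]
  post <- panels[panels$window == "post", ]
  merged <- dplyr::inner_join(pre, post, by = "patient_id",
    suffix = c("_pre", "_post"))
  res <- compare_paired(merged$twag_pre, merged$twag_post)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$median_post, res$median_pre)
})

test_that("Fisher's exact test matches hypergeometric enumeration and handles empty margins", {
  expect_equal(fisher_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  res <- fisher_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  set.seed(91)
  for (i in 1:25) {
    m <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_2x2(m)$p_value, oracle_fisher_p(m),
      tolerance = 1e-9)
  }
})

test_that("tests hold their nominal size under the null", {
  set.seed(103)
  n_rep <- 1000
  rej <- c(rank = 0, paired = 0, fisher = 0)
  for (i in seq_len(n_rep)) {
    a <- rnorm(20)
    b <- rnorm(20)
    if (compare_unpaired(a, b, family = "rank")$p_value < 0.05) {
      rej["rank"] <- rej["rank"] + 1
    }
    if (compare_paired(rnorm(20), rnorm(20))$p_value < 0.05) {
      rej["paired"] <- rej["paired"] + 1
    }
    k <- rbinom(2, 60, 0.5)
    tab <- matrix(c(k[1], 60 - k[1], k[2], 60 - k[2]), 2, byrow = TRUE)
    if (fisher_2x2(tab)$p_value < 0.05) {
      rej["fisher"] <- rej["fisher"] + 1
    }
  }
  rates <- rej / n_rep
  expect_true(all(rates[c("rank", "paired")] >= 0.03))
  expect_true(all(rates <= 0.07))
  # Fisher's conditional test is conservative by construction
  expect_gte(rates[["fisher"]], 0.01)
})

test_that("bootstrap-t comparison is seed-stable and sane on shifted groups", {
  set.seed(113)
  a <- rexp(25)
  b <- rexp(25) + 1.2
  r1 <- compare_unpaired(a, b, family = "bootstrap_t", n_boot = 2000,
    seed = 7)
  r2 <- compare_unpaired(a, b, family = "bootstrap_t", n_boot = 2000,
    seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_lt(r1$p_value, 0.01)
  same <- compare_unpaired(a, a, family = "bootstrap_t", n_boot = 500,
    seed = 7)
  expect_gt(same$p_value, 0.5)
})

test_that("correlated predictors collapse to the most predictive member", {
  set.seed(123)
  n <- 300
  x1 <- rnorm(n)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n) # r about 0.9 with x1
  x3 <- rnorm(n) # independent
  y <- rbinom(n, 1, plogis(1.2 * x1))
  d <- data.frame(y = y, x1 = x1, x2 = x2, x3 = x3)
  scr <- screen_predictors(d, "y")
  expect_true("x1" %in% scr$retained)
  expect_false("x2" %in% scr$retained)
  expect_true("x3" %in% scr$retained)
  expect_true(any(scr$log$action == "correlated_pair"))

  # duplicated predictor: exactly one copy survives
  d2 <- data.frame(y = y, a = x1, b = x1)
  scr2 <- screen_predictors(d2, "y")
  expect_equal(length(scr2$retained), 1)

  # uncorrelated predictors are all retained, in any column order
  d3 <- data.frame(y = y, p = rnorm(n), q = rnorm(n), r = x3)
  expect_setequal(screen_predictors(d3, "y")$retained, c("p", "q", "r"))
  d3perm <- d3[c("y", "r", "q", "p")]
  expect_setequal(screen_predictors(d3perm, "y")$retained, c("p", "q", "r"))

  # constants are excluded with a log entry
  d4 <- data.frame(y = y, c1 = rep(2, n), x = x1)
  scr4 <- screen_predictors(d4, "y")
  expect_equal(scr4$retained, "x")
  expect_true(any(scr4$log$action == "exclude_constant"))
})

test_that("transitive correlation chains resolve to a single representative", {
  set.seed(133)
  n <- 400
  base <- rnorm(n)
  a <- base + 0.55 * rnorm(n)
  b <- base + 0.55 * rnorm(n) # a~b, a~c, b~c all above 0.5
  c <- base + 0.55 * rnorm(n)
  y <- rbinom(n, 1, plogis(a))
  scr <- screen_predictors(data.frame(y = y, a = a, b = b, c = c), "y")
  expect_equal(length(scr$retained), 1)
})

test_that("logistic cascade: null behaviour, gating, and brute-force agreement", {
  set.seed(143)
  n <- 500
  d <- data.frame(
    y = rbinom(n, 1, 0.4),
    sig = NA, noise = rnorm(n)
  )
  d$sig <- rnorm(n, mean = d$y) # informative
  fit <- logistic_cascade(d, "y", c("sig", "noise"))
  or_noise <- fit$univariate$or[fit$univariate$term == "noise"]
  expect_lt(abs(or_noise - 1), 0.3)
  expect_true("sig" %in% fit$entered)
  expect_false("noise" %in% fit$entered)
  expect_equal(fit$multivariable$term, "sig")
  expect_true(all(fit$univariate$ci_low <= fit$univariate$or &
    fit$univariate$or <= fit$univariate$ci_high))

  # tiny fixture: coefficients equal direct likelihood maximisation
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(0, 1, 0, 1, 1, 1)
  fit6 <- logistic_cascade(data.frame(y = y, x = x), "y", "x",
    p_enter = 1.01)
  beta_oracle <- oracle_logistic_fit(x, y)
  expect_equal(fit6$univariate$estimate, beta_oracle[2], tolerance = 5e-4)
})

test_that("interrupted time-series recovers exact steps and flags short segments", {
  k <- c(-5:-1, 1:5)
  flat <- interrupted_time_series(k, rep(100, 10))
  expect_equal(flat$level_change, 0)
  expect_equal(flat$pre_slope, 0)

  stepped <- interrupted_time_series(k, c(rep(100, 5), rep(120, 5)))
  expect_equal(stepped$level_change, 20)
  expect_equal(stepped$pre_slope, 0)
  expect_equal(stepped$post_slope, 0)

  sloped <- interrupted_time_series(k, 2 * k + 30 * (k > 0))
  expect_equal(sloped$pre_slope, 2)
  expect_equal(sloped$post_slope, 2)
  expect_equal(sloped$level_change, 30, tolerance = 1e-9)

  expect_error(interrupted_time_series(c(-1, -2, 1:5), rnorm(7)),
    "at least 3")
})
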
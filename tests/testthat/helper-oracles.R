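# Independent brute-force oracles used to pin the analytic implementations.
# These deliberately avoid the code paths they check.

# worked example: 30-h pre-event trace, 120 mg/dL every 2 h with two
# 150 mg/dL excursions at t = 7 h and t = 19 h, so that exactly the
# second and fourth of five 6-h periods are dysglycemic at 70-140
figure_style_trace <- function() {
  t <- sort(c(seq(0, 30, by = 2), 7, 19))
  v <- ifelse(t %in% c(7, 19), 150, 120)
  make_fixture_trace(t, v)
}

random_trace <- function(n = NULL) {
  if (is.null(n)) n <- sample(3:30, 1)
  t <- cumsum(runif(n, 0.3, 6))
  v <- runif(n, 60, 250)
  list(time_h = t, glucose_mgdl = v)
}

# dense trapezoidal integration of the piecewise-linear interpolant
oracle_twag_dense <- function(time_h, glucose_mgdl, step = 0.001) {
  span <- max(time_h) - min(time_h)
  grid <- seq(min(time_h), max(time_h),
    length.out = max(ceiling(span / step), 2) + 1)
  v <- approx(time_h, glucose_mgdl, xout = grid)$y
  dt <- diff(grid)
  sum(dt * (head(v, -1) + tail(v, -1)) / 2) / span
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_rank_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_of <- function(idx) {
    xa <- pooled[idx]
    xb <- pooled[-idx]
    sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  }
  u_obs <- u_of(seq_len(na))
  u_all <- apply(utils::combn(n, na), 2, u_of)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# exact two-sided signed-rank p by enumerating all 2^n sign flips
oracle_signed_rank_p <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# two-sided Fisher p by direct hypergeometric enumeration
oracle_fisher_p <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ])
  c1 <- sum(m[, 1])
  n <- sum(m)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(support, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# logistic log-likelihood maximised numerically, independent of glm
oracle_logistic_fit <- function(x, y) {
  nll <- function(beta) {
    eta <- beta[1] + beta[2] * x
    -sum(y * eta - log1p(exp(eta)))
  }
  optim(c(0, 0), nll, method = "BFGS",
    control = list(maxit = 1000, reltol = 1e-12))$par
}
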
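# Independent oracles used to cross-check the package's fitting code.
# These deliberately avoid the package's own code paths.

# Least squares via explicitly solved normal equations.
ols_oracle <- function(X, y) {
  b <- solve(t(X) %*% X, t(X) %*% y)
  list(coef = drop(b), residuals = drop(y - X %*% b))
}

# Maximum-likelihood logistic regression via hand-rolled Newton-Raphson/IRLS.
irls_logit_oracle <- function(X, y, tol = 1e-12, max_iter = 100) {
  b <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    score <- t(X) %*% (y - p)
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% b)
  p <- 1 / (1 + exp(-eta))
  list(coef = b, fitted = p, residuals = y - p)
}

# Brute-force cosinor: grid over acrophase phi (default 0.01 h resolution);
# at each phi the best mesor/amplitude for y ~ M + A*cos(w(t - phi)) follow
# from simple 2-variable least squares sums. Rows with negative A are
# excluded when picking the minimum (the equivalent phi + 12 entry has A >= 0
# and the same SSE).
grid_cosinor_oracle <- function(y, t, phi_step = 0.01) {
  phis <- seq(0, 24 - phi_step, by = phi_step)
  w <- 2 * pi / 24
  n <- length(y)
  ybar <- mean(y)
  syy <- sum((y - ybar)^2)
  # cos(w(t - phi)) = cos(wt)cos(w phi) + sin(wt)sin(w phi)
  ct <- cos(w * t); st <- sin(w * t)
  cp <- cos(w * phis); sp <- sin(w * phis)
  s_c <- cp * sum(ct) + sp * sum(st)              # sum of c_i per phi
  s_cc <- cp^2 * sum(ct^2) + 2 * cp * sp * sum(ct * st) + sp^2 * sum(st^2)
  s_cy <- cp * sum(ct * y) + sp * sum(st * y)
  sxx <- s_cc - s_c^2 / n
  sxy <- s_cy - s_c * sum(y) / n
  A <- sxy / sxx
  sse <- syy - sxy^2 / sxx
  ok <- A >= 0
  best <- which(ok)[which.min(sse[ok])]
  list(phi = phis[best], A = A[best],
       M = ybar - A[best] * s_c[best] / n,
       sse = sse[best], r2_pct = 100 * (1 - sse[best] / syy))
}

# Small labelled dataset of demographics for residualization tests.
make_demo_data <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    y = rnorm(n),
    g3 = sample(c("a", "b", "c"), n, replace = TRUE),
    g2 = sample(c("x", "y"), n, replace = TRUE),
    local_hours = runif(n, 0, 24),
    local_date = as.Date("2012-01-01") + sample(0:120, n, replace = TRUE)
  )
}

# Localize + recode a simulated table: the standard preprocessing steps used
# throughout the tests.
prep_sim <- function(df, zt = default_zone_table()) {
  df <- suppressMessages(localize_records(df, zt$zones, zt$server))
  df <- exclude_transition_days(df, zt$zones)
  df$d_ingroup <- recode_ingroup(df$d_raw, df$race)
  df$is_female <- as.integer(df$gender == "female")
  df
}
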
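test_that("a noiseless cosine is recovered exactly", {
  t <- seq(0, 24, length.out = 481)[-481]
  y <- 2 * cos(2 * pi * (t - 21.17) / 24)
  fit <- fit_cosinor(residual_series(y, t))
  expect_equal(fit$amplitude, 2, tolerance = 1e-9)
  expect_equal(fit$acrophase_hours, 21.17, tolerance = 1e-9)
  expect_equal(fit$r2_pct, 100)
  expect_equal(fit$p, 0)
})

test_that("a constant series has zero amplitude, r2, and F", {
  fit <- fit_cosinor(residual_series(rep(1.5, 20), seq(0.5, 23.5, length.out = 20)))
  expect_equal(fit$amplitude, 0, tolerance = 1e-12)
  expect_equal(fit$r2_pct, 0)
  expect_equal(fit$f_stat, 0)
  expect_true(is.na(fit$acrophase_hours))
})

test_that("acrophase algebra covers all quadrants", {
  expect_equal(acrophase_from_coefs(0, 1), 0)
  expect_equal(acrophase_from_coefs(1, 0), 6)
  expect_equal(acrophase_from_coefs(-1, 0), 18)
  expect_equal(acrophase_from_coefs(0, -1), 12)
  expect_error(acrophase_from_coefs(0, 0), "undefined")
})

test_that("degenerate time designs are rejected", {
  expect_error(fit_cosinor(residual_series(rnorm(20), rep(c(1, 2), 10))),
               "singular")
  expect_error(fit_cosinor(residual_series(rnorm(5), 1:5)), "at least 10")
})

test_that("fit agrees with the brute-force grid-search oracle", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(200:800, 1)
    t <- runif(n, 0, 24)
    phi <- runif(1, 0, 24)
    y <- runif(1, -1, 1) + runif(1, 0.5, 2) * cos(2 * pi * (t - phi) / 24) +
      rnorm(n, 0, 1)
    fit <- fit_cosinor(residual_series(y, t))
    oracle <- grid_cosinor_oracle(y, t)
    expect_lt(abs(circular_diff_hours(fit$acrophase_hours, oracle$phi)), 0.011)
    expect_lt(abs(fit$amplitude - oracle$A), 1e-3)
    expect_lt(abs(fit$mesor - oracle$M), 1e-3)
    expect_lt(abs(fit$r2_pct - oracle$r2_pct), 1e-4)
  }
})

test_that("r2 and F satisfy their closed-form identities", {
  set.seed(12)
  t <- runif(500, 0, 24)
  y <- 0.3 * cos(2 * pi * (t - 5) / 24) + rnorm(500)
  fit <- fit_cosinor(residual_series(y, t))
  # independent two-pass variance decomposition
  pred <- fit$mesor + fit$beta_sin * sin(2 * pi * t / 24) +
    fit$beta_cos * cos(2 * pi * t / 24)
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(fit$r2_pct, 100 * (1 - sse / sst), tolerance = 1e-8)
  r2 <- fit$r2_pct / 100
  expect_equal(fit$f_stat, (r2 / 2) / ((1 - r2) / (fit$n - 3)), tolerance = 1e-8)
  # amplitude/acrophase form and the linear form are the same curve
  expect_equal(predict_curve(fit, t), pred, tolerance = 1e-10)
})

test_that("time-shifted data shifts the acrophase and nothing else", {
  set.seed(13)
  t <- runif(1000, 0, 24)
  y <- 1 + 0.5 * cos(2 * pi * (t - 10) / 24) + rnorm(1000, 0, 0.5)
  f0 <- fit_cosinor(residual_series(y, t))
  delta <- 5.25
  f1 <- fit_cosinor(residual_series(y, wrap_hours(t + delta)))
  expect_equal(wrap_hours(f0$acrophase_hours + delta), f1$acrophase_hours,
               tolerance = 1e-8)
  expect_lt(abs(f0$amplitude - f1$amplitude), 1e-8)
  expect_lt(abs(f0$r2_pct - f1$r2_pct), 1e-8)
  expect_lt(abs(f0$f_stat - f1$f_stat) / f0$f_stat, 1e-8)
})

test_that("predict_curve peaks at the acrophase", {
  fit <- structure(list(mesor = 0, amplitude = 1, acrophase_hours = 0,
                        beta_sin = 0, beta_cos = 1),
                   class = "cosinor_fit")
  expect_equal(predict_curve(fit, 0), 1)
  expect_equal(predict_curve(fit, 12), -1)
  fit$mesor <- 2; fit$amplitude <- 0.7; fit$acrophase_hours <- 9.3
  expect_equal(predict_curve(fit, 9.3), 2.7)
})

test_that("moderation recovers a built-in two-group acrophase shift", {
  set.seed(14)
  n <- 40000
  t <- runif(n, 0, 24)
  grp <- rep(c("m", "w"), length.out = n)
  phi <- ifelse(grp == "w", 19, 21)
  y <- 0.4 * cos(2 * pi * (t - phi) / 24) + rnorm(n, 0, 1)
  res <- moderation_test(residual_series(y, t), grp, "categorical")
  expect_lt(res$p, 1e-6)
  # level order m, w: shift = w - m = -2 h
  expect_equal(unname(res$acrophase_shift_hours), -2, tolerance = 0.25)
  expect_equal(res$df[1], 2)
  expect_equal(res$level_fits$w$acrophase_hours, 19, tolerance = 0.25)
})

test_that("continuous moderation reports implied rhythms at reference values", {
  set.seed(15)
  n <- 30000
  t <- runif(n, 0, 24)
  x <- runif(n, 0, 10)
  y <- (1 + 0.05 * x) * cos(2 * pi * (t - 8) / 24) + rnorm(n, 0, 0.8)
  res <- moderation_test(residual_series(y, t), x, "continuous",
                         ref_values = c(0, 10))
  expect_lt(res$p, 1e-6)
  amps <- vapply(res$level_fits, function(f) f$amplitude, numeric(1))
  expect_equal(unname(amps), c(1, 1.5), tolerance = 0.1)
  # same acrophase at both ends: shift near zero
  expect_lt(abs(res$acrophase_shift_hours), 0.25)
})

test_that("moderation rejects constant moderators and drops tiny levels", {
  s <- residual_series(rnorm(500), runif(500, 0, 24))
  expect_error(moderation_test(s, rep("a", 500), "categorical"), "constant")
  expect_error(moderation_test(s, rep(3, 500), "continuous"), "constant")
  m <- c(rep("big", 480), rep("small", 20))
  expect_warning(expect_error(moderation_test(s, m, "categorical"),
                              "constant after"),
                 "below min_level_n")
})
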
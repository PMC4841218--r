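# Build a residual series with a per-age acrophase rule.
make_age_series <- function(n_per_age, ages, phi_fun, r2 = 0.3, seed = 1) {
  set.seed(seed)
  age <- rep(ages, each = n_per_age)
  n <- length(age)
  t <- runif(n, 0, 24)
  A <- sqrt(2 * r2 / (1 - r2))  # noise sd 1
  y <- A * cos(2 * pi * (t - phi_fun(age)) / 24) + rnorm(n)
  list(series = residual_series(y, t), age = age)
}

test_that("identical rhythms give equal acrophases across strata", {
  # near-noiseless rhythm so each stratum pins the phase to within minutes
  d <- make_age_series(5000, 18:25, function(a) 20, r2 = 0.98, seed = 21)
  curve <- acrophase_by_stratum(d$series, d$age, c(18, 25))
  expect_equal(nrow(curve$strata), 8L)
  spread <- max(abs(circular_diff_hours(curve$strata$acrophase_hours, 20)))
  expect_lt(spread, 2 / 60)  # within ±2 minutes at n=5,000 per stratum
})

test_that("an injected linear phase delay yields a monotone-increasing curve", {
  d <- make_age_series(4000, 18:30, function(a) 10 + 0.25 * (a - 18),
                       r2 = 0.9, seed = 22)
  curve <- acrophase_by_stratum(d$series, d$age, c(18, 30))
  phi <- unwrap_acrophases(curve$strata$acrophase_hours, curve$strata$n_obs)
  expect_true(all(diff(phi) > 0))
})

test_that("small strata are dropped with a warning; none left is an error", {
  d <- make_age_series(40, 18:20, function(a) 20, seed = 23)
  expect_error(
    suppressWarnings(acrophase_by_stratum(d$series, d$age, c(18, 20), min_n = 41)),
    "no age stratum"
  )
  expect_warning(
    curve <- acrophase_by_stratum(d$series, c(rep(18L, 80), d$age[-(1:80)]),
                                  c(18, 20), min_n = 50),
    "below min_n"
  )
  expect_equal(curve$strata$age_years, 18L)
  expect_error(weighted_acrophase_regression(curve), "at least 3")
})

test_that("exactly linear acrophases give slope exact and weighted r2 = 100", {
  strata <- data.frame(age_years = 18:30,
                       acrophase_hours = 20 + 0.05 * (18:30 - 18),
                       n_obs = sample(50:500, 13))
  fit <- weighted_acrophase_regression(strata)
  expect_equal(fit$slope_min_per_year, 3, tolerance = 1e-9)
  expect_equal(fit$weighted_r2_pct, 100, tolerance = 1e-9)
})

test_that("equal weights reproduce the ordinary least-squares oracle", {
  set.seed(24)
  strata <- data.frame(age_years = 18:40,
                       acrophase_hours = wrap_hours(21 + 0.04 * (18:40) + rnorm(23, 0, 0.1)),
                       n_obs = rep(100, 23))
  fit <- weighted_acrophase_regression(strata)
  phi <- unwrap_acrophases(strata$acrophase_hours, strata$n_obs)
  X <- cbind(1, strata$age_years)
  oracle <- ols_oracle(X, phi)
  expect_equal(fit$slope_min_per_year, 60 * oracle$coef[2], tolerance = 1e-9)
  expect_equal(fit$intercept_hours, oracle$coef[1], tolerance = 1e-9)
})

test_that("rescaling all weights leaves the fit unchanged", {
  strata <- data.frame(age_years = 18:28,
                       acrophase_hours = 19 + 0.1 * sin(18:28),
                       n_obs = c(55, 120, 300, 80, 240, 60, 500, 75, 90, 110, 130))
  f1 <- weighted_acrophase_regression(strata)
  strata$n_obs <- strata$n_obs * 2L
  f2 <- weighted_acrophase_regression(strata)
  expect_equal(f1$slope_min_per_year, f2$slope_min_per_year, tolerance = 1e-10)
  expect_equal(f1$intercept_hours, f2$intercept_hours, tolerance = 1e-10)
  expect_equal(f1$weighted_r2_pct, f2$weighted_r2_pct, tolerance = 1e-10)
})

test_that("identical acrophases give zero slope and zero r2, not an error", {
  strata <- data.frame(age_years = 18:22, acrophase_hours = rep(21, 5),
                       n_obs = c(60, 70, 80, 90, 100))
  fit <- weighted_acrophase_regression(strata)
  expect_equal(fit$slope_min_per_year, 0, tolerance = 1e-10)
  expect_equal(fit$weighted_r2_pct, 0, tolerance = 1e-10)
})

test_that("unwrapping prevents artificial 24-hour jumps around midnight", {
  # acrophases straddle midnight: 23.5, 23.8, 0.1, 0.4 should unwrap smoothly
  strata <- data.frame(age_years = 18:21,
                       acrophase_hours = c(23.5, 23.8, 0.1, 0.4),
                       n_obs = rep(100, 4))
  fit <- weighted_acrophase_regression(strata)
  expect_equal(fit$slope_min_per_year, 0.3 * 60 / 1, tolerance = 1e-6)
  expect_equal(fit$weighted_r2_pct, 100, tolerance = 1e-6)
})

test_that("continuous-age moderation recovers endpoint acrophase differences", {
  d <- make_age_series(3000, 18:40, function(a) 14 + (1 / 22) * (a - 18),
                       r2 = 0.15, seed = 25)
  res <- continuous_age_moderation(d$series, d$age, c(18, 40))
  expect_lt(res$p, 1e-4)
  expect_equal(res$endpoint_shift_hours, 1, tolerance = 0.25)
  # null case: no age dependence
  d0 <- make_age_series(3000, 18:40, function(a) 14, r2 = 0.15, seed = 26)
  res0 <- continuous_age_moderation(d0$series, d0$age, c(18, 40))
  expect_lt(abs(res0$endpoint_shift_hours), 0.25)
  expect_error(continuous_age_moderation(d$series, rep(20, d$series$n), c(18, 40)),
               "constant")
})

test_that("stratified and continuous age summaries agree in sign", {
  for (sl in c(0.05, -0.05)) {
    d <- make_age_series(2000, 18:32, function(a) 14 + sl * (a - 18),
                         r2 = 0.2, seed = 27)
    curve <- weighted_acrophase_regression(
      acrophase_by_stratum(d$series, d$age, c(18, 32), min_n = 50))
    res <- continuous_age_moderation(d$series, d$age, c(18, 32))
    expect_equal(sign(curve$slope_min_per_year), sign(sl))
    expect_equal(sign(res$endpoint_shift_hours), sign(sl))
  }
})
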
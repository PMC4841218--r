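test_that("the same seed reproduces the table bit-for-bit", {
  a <- simulate_participants(scenario_preset("mixed", n = 3000, seed = 41))
  b <- simulate_participants(scenario_preset("mixed", n = 3000, seed = 41))
  expect_identical(a, b)
  c <- simulate_participants(scenario_preset("mixed", n = 3000, seed = 42))
  expect_false(identical(a$d_raw, c$d_raw))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(100, 1, race_props = c(White = 0.9, Black = 0.2)),
               "sum to 1")
  expect_error(sim_config(100, 1, p_female = 1.4), "proportion")
  expect_error(sim_config(100, 1,
                          circadian = list(target_r2_pct = -1,
                                           acrophase_hours = 21,
                                           dst_shift_min = 0,
                                           gender_shift_min = 0,
                                           age_slope_min_per_year = 0,
                                           age_ref = 18)),
               "target_r2_pct")
  expect_error(scenario_preset("nonsense"), "valid presets")
})

test_that("demographic marginals match the configuration at n = 100,000", {
  cfg <- scenario_preset("null", n = 100000, seed = 43)
  df <- simulate_participants(cfg)
  expect_lt(abs(mean(df$gender == "female") - cfg$p_female), 0.005)
  props <- table(df$race) / nrow(df)
  for (g in names(cfg$race_props)) {
    expect_lt(abs(props[[g]] - cfg$race_props[[g]]), 0.005)
  }
  expect_true(all(df$age >= 18 & df$age <= 89))
})

test_that("the age distribution matches its truncated-gamma law (chi-square GOF)", {
  cfg <- scenario_preset("null", n = 100000, seed = 44)
  df <- simulate_participants(cfg)
  a <- cfg$age
  ages <- a$min:a$max
  # age = min + floor(g), g ~ Gamma(shape, scale), redrawn while age > max
  p_upper <- pgamma(a$max - a$min + 1, shape = a$shape, scale = a$scale)
  pmf <- (pgamma(ages - a$min + 1, shape = a$shape, scale = a$scale) -
            pgamma(ages - a$min, shape = a$shape, scale = a$scale)) / p_upper
  obs <- tabulate(df$age - a$min + 1L, nbins = length(ages))
  # pool the sparse old-age tail so expected counts stay reasonable
  keep <- pmf * nrow(df) >= 5
  if (any(!keep)) {
    obs <- c(obs[keep], sum(obs[!keep]))
    pmf <- c(pmf[keep], sum(pmf[!keep]))
  }
  gof <- suppressWarnings(chisq.test(obs, p = pmf, rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
})

test_that("participation times follow the configured bin histogram", {
  cfg <- scenario_preset("null", n = 100000, seed = 45)
  df <- prep_sim(simulate_participants(cfg))
  obs <- tabulate(floor(df$local_hours) + 1L, nbins = 24) / nrow(df)
  expect_lt(max(abs(obs - cfg$time_bins)), 0.01)
})

test_that("emitted timestamps reproduce the latent local clock times", {
  cfg <- scenario_preset("circadian", n = 20000, seed = 46)
  df <- simulate_participants(cfg)
  lat <- attr(df, "latent")
  lr <- suppressMessages(localize_records(df, cfg$zone_table$zones,
                                          cfg$zone_table$server))
  err <- abs(circular_diff_hours(lr$local_hours, lat$local_hours))
  # a handful of records adjacent to DST transitions may land an hour off;
  # transition days are excluded from analysis anyway
  expect_gt(mean(err < 1e-9), 0.999)
})

test_that("with no rhythm and no selection, cosinor p-values are uniform", {
  # Kolmogorov-Smirnov over 1,000 null replicates of n = 2,000
  pvals <- vapply(1:1000, function(i) {
    cfg <- scenario_preset("null", n = 2000, seed = 46000 + i)
    df <- simulate_participants(cfg)
    lat <- attr(df, "latent")
    df$local_hours <- lat$local_hours
    df$local_date <- lat$local_date
    df$d_ingroup <- recode_ingroup(df$d_raw, df$race)
    s <- adjust_continuous(df, "d_ingroup",
                           adjustment_spec("race", detrend = FALSE))
    fit_cosinor(s)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the injected target r2 is realized in a large sample", {
  # circadian preset: outcome structure is race means + rhythm + noise, so
  # adjusting for race isolates the rhythm against its intended variance base
  cfg <- scenario_preset("circadian", n = 1000000, seed = 47)
  df <- simulate_participants(cfg)
  lat <- attr(df, "latent")
  df$local_hours <- lat$local_hours
  df$d_ingroup <- recode_ingroup(df$d_raw, df$race)
  s <- adjust_continuous(df, "d_ingroup", adjustment_spec("race", detrend = FALSE))
  fit <- fit_cosinor(s)
  expect_lt(abs(fit$r2_pct - 0.08) / 0.08, 0.10)
})

test_that("preset phase modifiers act in the documented directions", {
  # women earlier under gender_phase_shift
  cfg <- scenario_preset("gender_phase_shift", n = 60000, seed = 48)
  df <- simulate_participants(cfg)
  lat <- attr(df, "latent")
  d <- recode_ingroup(df$d_raw, df$race)
  fw <- fit_cosinor(residual_series(d[df$gender == "female"],
                                    lat$local_hours[df$gender == "female"]))
  fm <- fit_cosinor(residual_series(d[df$gender == "male"],
                                    lat$local_hours[df$gender == "male"]))
  expect_lt(circular_diff_hours(fw$acrophase_hours, fm$acrophase_hours), 0)

  # DST-period peak earlier under dst_phase_shift
  cfg <- scenario_preset("dst_phase_shift", n = 120000, seed = 49)
  df <- simulate_participants(cfg)
  lat <- attr(df, "latent")
  d <- recode_ingroup(df$d_raw, df$race)
  fd <- fit_cosinor(residual_series(d[lat$dst], lat$local_hours[lat$dst]))
  fn <- fit_cosinor(residual_series(d[!lat$dst], lat$local_hours[!lat$dst]))
  expect_lt(circular_diff_hours(fd$acrophase_hours, fn$acrophase_hours), 0)
})
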
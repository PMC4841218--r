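#' Model the rhythm separately for each year of age
#'
#' To avoid assuming a shape for the age-acrophase relationship, the cosinor
#' is fit within each integer year of age and the predicted acrophase is
#' saved together with the number of contributing observations. Strata with
#' fewer observations than `min_n` are dropped with a warning.
#'
#' @param series A [residual_series()].
#' @param age Integer ages per record (same length as the series).
#' @param age_range Two-element vector `(lo, hi)`; ages outside are ignored.
#' @param min_n Minimum observations per retained stratum (default 50).
#' @return An object of class `"acrophase_curve"` whose `strata` element is a
#'   data.frame with columns `age_years`, `acrophase_hours`, `amplitude`, and
#'   `n_obs`; the regression summary fields (`slope_min_per_year`,
#'   `intercept_hours`, `weighted_r2_pct`) are `NA` until
#'   [weighted_acrophase_regression()] is applied.
#' @export
acrophase_by_stratum <- function(series, age, age_range = c(18, 89), min_n = 50) {
  stopifnot(inherits(series, "residual_series"), length(age) == series$n,
            length(age_range) == 2L, age_range[1] <= age_range[2])
  age <- as.integer(round(age))
  ages <- seq.int(age_range[1], age_range[2])
  rows <- list()
  dropped <- integer(0)
  for (a in ages) {
    sel <- !is.na(age) & age == a
    n_a <- sum(sel)
    if (n_a == 0L) next
    if (n_a < min_n) { dropped <- c(dropped, a); next }
    fit <- fit_cosinor(residual_series(series$residual[sel], series$time[sel]))
    rows[[length(rows) + 1L]] <- data.frame(
      age_years = a, acrophase_hours = fit$acrophase_hours,
      amplitude = fit$amplitude, n_obs = n_a
    )
  }
  if (length(dropped) > 0L)
    warning(sprintf("dropped %d age stratum/strata below min_n = %d: %s",
                    length(dropped), min_n,
                    paste(dropped, collapse = ", ")), call. = FALSE)
  if (length(rows) == 0L)
    stop("no age stratum meets the minimum observation count", call. = FALSE)
  strata <- do.call(rbind, rows)
  structure(
    list(strata = strata, slope_min_per_year = NA_real_,
         intercept_hours = NA_real_, weighted_r2_pct = NA_real_),
    class = "acrophase_curve"
  )
}

#' Weighted regression of per-stratum acrophase on age
#'
#' Weighted least squares of the per-age acrophase on age, with weights equal
#' to the number of contributing observations, summarising how the clock time
#' of the rhythm's peak drifts with age. Before fitting, acrophases are
#' unwrapped onto the 24-hour branch closest to their circular mean, so that
#' a rhythm peaking near midnight does not produce artificial 24-hour jumps.
#'
#' @param curve An [acrophase_by_stratum()] result, or a data.frame with
#'   columns `age_years`, `acrophase_hours`, `n_obs`.
#' @return The `acrophase_curve` with `slope_min_per_year` (minutes of
#'   acrophase delay per year of age), `intercept_hours`, and
#'   `weighted_r2_pct` filled in, plus the unwrapped acrophases in
#'   `strata$acrophase_unwrapped`.
#' @export
weighted_acrophase_regression <- function(curve) {
  if (is.data.frame(curve)) {
    curve <- structure(list(strata = curve, slope_min_per_year = NA_real_,
                            intercept_hours = NA_real_,
                            weighted_r2_pct = NA_real_),
                       class = "acrophase_curve")
  }
  stopifnot(inherits(curve, "acrophase_curve"))
  s <- curve$strata
  if (nrow(s) < 3L)
    stop("acrophase regression needs at least 3 age strata", call. = FALSE)
  if (any(s$n_obs <= 0)) stop("stratum weights must be positive", call. = FALSE)
  phi <- unwrap_acrophases(s$acrophase_hours, s$n_obs)
  w <- s$n_obs
  x <- s$age_years
  fit <- stats::lm(phi ~ x, weights = w)
  b <- stats::coef(fit)
  wmean <- sum(w * phi) / sum(w)
  sst_w <- sum(w * (phi - wmean)^2)
  sse_w <- sum(w * stats::residuals(fit)^2)
  curve$strata$acrophase_unwrapped <- phi
  curve$slope_min_per_year <- unname(b["x"]) * 60
  curve$intercept_hours <- unname(b["(Intercept)"])
  curve$weighted_r2_pct <- if (sst_w > 0) 100 * (1 - sse_w / sst_w) else 0
  curve
}

# Map acrophases to the 24-h branch nearest the (weighted) circular mean, so
# linear regression sees a continuous quantity.
unwrap_acrophases <- function(phi, w = NULL) {
  centre <- circular_mean_hours(phi, w)
  if (is.na(centre)) centre <- mean(phi)
  centre + circular_diff_hours(phi, centre)
}

#' Continuous-age moderation of the rhythm with endpoint acrophases
#'
#' Sensitivity companion to the stratified analysis: fits linear age directly
#' into the cosinor model via [moderation_test()] (continuous kind) within
#' `age_range`, and reports the implied acrophase at the two range endpoints
#' and their signed circular difference.
#'
#' @inheritParams acrophase_by_stratum
#' @return The [moderation_test()] result, with extra elements
#'   `endpoint_ages`, `endpoint_acrophases`, and `endpoint_shift_hours`
#'   (acrophase at `hi` minus at `lo`, wrapped to `(-12, 12]`).
#' @export
continuous_age_moderation <- function(series, age, age_range = c(18, 40)) {
  stopifnot(inherits(series, "residual_series"), length(age) == series$n)
  sel <- !is.na(age) & age >= age_range[1] & age <= age_range[2]
  if (sum(sel) == 0L) stop("no records within age_range", call. = FALSE)
  sub <- residual_series(series$residual[sel], series$time[sel])
  res <- moderation_test(sub, age[sel], kind = "continuous",
                         ref_values = as.numeric(age_range))
  res$endpoint_ages <- as.numeric(age_range)
  res$endpoint_acrophases <- unname(vapply(res$level_fits,
                                           function(f) f$acrophase_hours,
                                           numeric(1)))
  res$endpoint_shift_hours <- circular_diff_hours(res$endpoint_acrophases[2L],
                                                  res$endpoint_acrophases[1L])
  res
}

#' @export
print.acrophase_curve <- function(x, ...) {
  cat(sprintf("Acrophase-by-age curve: %d strata (ages %d-%d)\n",
              nrow(x$strata), min(x$strata$age_years), max(x$strata$age_years)))
  if (!is.na(x$slope_min_per_year)) {
    cat(sprintf("  weighted fit: %+.3f min/year, intercept %.2f h, weighted r2 %.2f%%\n",
                x$slope_min_per_year, x$intercept_hours, x$weighted_r2_pct))
  }
  invisible(x)
}
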
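#' Cosinor fit to a fixed person-level variable
#'
#' Age and gender cannot oscillate within a day, so any 24-hour "rhythm" a
#' cosinor finds in them measures pure selection: systematic differences in
#' who participates at different clock times. The variable is first
#' residualized on the remaining covariates (plus detrending) — continuous
#' variables via [adjust_continuous()], binary via [adjust_binary()] — and
#' the cosinor is then fit to those residuals, exactly as for the outcome.
#'
#' @param data Data.frame of localized participant records.
#' @param variable Column name of the fixed variable to benchmark.
#' @param kind `"continuous"` or `"binary"`.
#' @param spec An [adjustment_spec()] giving the covariates to residualize
#'   on; listing `variable` among its own covariates is a configuration
#'   error.
#' @param time_col,date_col Column names, as in [adjust_continuous()].
#' @return A [fit_cosinor()] result for the residualized variable.
#' @export
benchmark_fixed_variable <- function(data, variable,
                                     kind = c("continuous", "binary"),
                                     spec,
                                     time_col = "local_hours",
                                     date_col = "local_date") {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "adjustment_spec"))
  if (variable %in% spec$categorical_covariates)
    stop(sprintf("configuration error: '%s' appears among its own covariates",
                 variable), call. = FALSE)
  series <- if (kind == "continuous") {
    adjust_continuous(data, variable, spec, time_col, date_col)
  } else {
    adjust_binary(data, variable, spec, time_col, date_col)
  }
  fit_cosinor(series)
}

#' Compare outcome rhythm strength against fixed-variable benchmarks
#'
#' For each benchmark variable the ratio `r2_benchmark / r2_outcome` is
#' formed: a ratio above 1 means the outcome's apparent rhythm explains less
#' variance than a variable that cannot have a rhythm at all, so the
#' outcome's time-of-day effect does not exceed what selection alone
#' produces.
#'
#' @param r2_outcome_pct Percent variance explained by the outcome's cosinor.
#' @param benchmark_fits Named list of [fit_cosinor()] results, or a named
#'   numeric vector of percent-variance values, one per benchmark variable.
#' @return An object of class `"benchmark_report"`: `r2_outcome_pct`, a
#'   data.frame `benchmarks` with columns `variable`, `r2_pct`,
#'   `acrophase_hours`, `ratio`, and a logical `outcome_r2_zero` flag. When
#'   `r2_outcome_pct` is 0 the ratios are `Inf` and the flag is set.
#' @export
benchmark_ratios <- function(r2_outcome_pct, benchmark_fits) {
  stopifnot(is.numeric(r2_outcome_pct), length(r2_outcome_pct) == 1L,
            r2_outcome_pct >= 0)
  if (is.numeric(benchmark_fits)) {
    vars <- names(benchmark_fits)
    if (is.null(vars)) vars <- paste0("benchmark", seq_along(benchmark_fits))
    r2 <- as.numeric(benchmark_fits)
    acro <- rep(NA_real_, length(r2))
  } else {
    vars <- names(benchmark_fits)
    r2 <- vapply(benchmark_fits, function(f) f$r2_pct, numeric(1))
    acro <- vapply(benchmark_fits, function(f) f$acrophase_hours, numeric(1))
  }
  if (any(r2 < 0)) stop("benchmark r2 values must be non-negative", call. = FALSE)
  zero <- r2_outcome_pct == 0
  ratio <- if (zero) rep(Inf, length(r2)) else r2 / r2_outcome_pct
  structure(
    list(r2_outcome_pct = r2_outcome_pct,
         benchmarks = data.frame(variable = vars, r2_pct = r2,
                                 acrophase_hours = acro, ratio = ratio,
                                 stringsAsFactors = FALSE),
         outcome_r2_zero = zero),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Selection-effect benchmark (outcome r2 = %.4f%%%s)\n",
              x$r2_outcome_pct,
              if (x$outcome_r2_zero) "; outcome rhythm absent, ratios infinite" else ""))
  b <- x$benchmarks
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %s: r2 = %.4f%%, acrophase %s, ratio = %.2f\n",
                b$variable[i], b$r2_pct[i],
                ifelse(is.na(b$acrophase_hours[i]), "NA",
                       hours_to_hhmm(b$acrophase_hours[i])),
                b$ratio[i]))
  }
  invisible(x)
}
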
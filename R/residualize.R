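#' Specification of the covariate adjustment applied before rhythm fitting
#'
#' The outcome is never modelled with covariates inside the cosinor itself;
#' instead covariate structure is regressed out first and the residuals are
#' analysed. The adjustment design contains an intercept, dummy codes for
#' each level of each categorical covariate (first level as reference), and,
#' if `detrend` is on, linear and quadratic study-day terms that remove
#' secular drift across the study period.
#'
#' @param categorical_covariates Character vector of column names; each is
#'   treated as categorical and expanded to indicator columns.
#' @param detrend Logical; include linear + quadratic study-day terms.
#' @param outcome_kind `"continuous"` or `"binary"`.
#' @return An object of class `"adjustment_spec"`.
#' @export
adjustment_spec <- function(categorical_covariates = character(),
                            detrend = TRUE,
                            outcome_kind = c("continuous", "binary")) {
  outcome_kind <- match.arg(outcome_kind)
  stopifnot(is.character(categorical_covariates), is.logical(detrend))
  structure(
    list(categorical_covariates = categorical_covariates,
         detrend = detrend, outcome_kind = outcome_kind),
    class = "adjustment_spec"
  )
}

#' Residual series: the input to cosinor fitting
#'
#' @param residual Numeric vector of residuals (or any outcome values to be
#'   rhythm-fitted directly).
#' @param time Clock times in decimal hours, same length.
#' @return An object of class `"residual_series"` with elements `residual`,
#'   `time`, `n`, and `total_ss` (sum of squared deviations of `residual`
#'   from its mean).
#' @export
residual_series <- function(residual, time) {
  stopifnot(length(residual) == length(time), is.numeric(residual), is.numeric(time))
  if (anyNA(residual) || anyNA(time))
    stop("residual_series does not accept missing values", call. = FALSE)
  structure(
    list(residual = as.numeric(residual), time = wrap_hours(as.numeric(time)),
         n = length(residual),
         total_ss = sum((residual - mean(residual))^2)),
    class = "residual_series"
  )
}

#' @export
print.residual_series <- function(x, ...) {
  cat(sprintf("Residual series: n = %d, mean = %.4g, total SS = %.6g\n",
              x$n, mean(x$residual), x$total_ss))
  invisible(x)
}

# Build the adjustment design matrix: intercept, covariate dummies, and
# (optionally) centered study-day terms scaled to [-1, 1] before squaring,
# for conditioning. Returns the matrix; rows must already be complete cases.
build_adjustment_design <- function(data, spec, date_col = "local_date") {
  stopifnot(inherits(spec, "adjustment_spec"))
  n <- nrow(data)
  parts <- list(`(Intercept)` = rep(1, n))
  X <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in spec$categorical_covariates) {
    if (!cv %in% names(data))
      stop(sprintf("covariate '%s' not found in data", cv), call. = FALSE)
    f <- factor(data[[cv]])
    if (nlevels(f) < 2L)
      stop(sprintf("covariate '%s' has fewer than 2 observed levels", cv), call. = FALSE)
    mm <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
    colnames(mm) <- paste0(cv, levels(f)[-1L])
    X <- cbind(X, mm)
  }
  if (spec$detrend) {
    if (!date_col %in% names(data))
      stop(sprintf("detrend requires a '%s' column", date_col), call. = FALSE)
    d <- as.numeric(as.Date(data[[date_col]]) - min(as.Date(data[[date_col]])))
    if (max(d) > 0) {
      sd1 <- 2 * d / max(d) - 1
      X <- cbind(X, study_day = sd1, study_day2 = sd1^2)
    }
  }
  X
}

# Shared row filter: complete cases over outcome + covariates (+ time/date),
# with a logged count of dropped rows.
complete_rows <- function(data, outcome_col, spec, time_col, date_col) {
  cols <- c(outcome_col, spec$categorical_covariates, time_col,
            if (spec$detrend) date_col)
  cols <- intersect(cols, names(data))
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    log_note("dropped %d record(s) with missing outcome/covariate values", n_drop)
  list(data = data[keep, , drop = FALSE], n_dropped = n_drop)
}

#' Regress covariates and secular trend out of a continuous outcome
#'
#' Fits ordinary least squares of the outcome on the adjustment design (see
#' [adjustment_spec()]) and returns the residuals paired with each record's
#' local clock time, ready for [fit_cosinor()]. Rows with missing values in
#' the outcome or any listed covariate are dropped with a logged count.
#' Aliased (rank-deficient) design columns are dropped with a warning.
#'
#' @param data Data.frame of participant records.
#' @param outcome_col Name of the numeric outcome column.
#' @param spec An [adjustment_spec()] with `outcome_kind = "continuous"`.
#' @param time_col,date_col Names of the local clock-time (decimal hours) and
#'   local date columns.
#' @return A [residual_series()]; attribute `n_dropped` counts removed rows.
#' @export
adjust_continuous <- function(data, outcome_col, spec,
                              time_col = "local_hours", date_col = "local_date") {
  stopifnot(inherits(spec, "adjustment_spec"))
  cr <- complete_rows(data, outcome_col, spec, time_col, date_col)
  data <- cr$data
  if (nrow(data) == 0L) stop("no rows left after missing-value filtering", call. = FALSE)
  y <- as.numeric(data[[outcome_col]])
  X <- build_adjustment_design(data, spec, date_col)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[is.na(fit$coefficients)]
    warning("rank-deficient adjustment design; dropped aliased column(s): ",
            paste(aliased, collapse = ", "), call. = FALSE)
  }
  out <- residual_series(fit$residuals, data[[time_col]])
  attr(out, "n_dropped") <- cr$n_dropped
  out
}

#' Regress covariates and secular trend out of a binary outcome
#'
#' Fits a maximum-likelihood logistic regression of a 0/1 outcome on the same
#' adjustment design as [adjust_continuous()] and returns response residuals
#' (observed minus fitted probability), so downstream variance-explained
#' computations use the same sums-of-squares logic as the continuous case.
#'
#' @inheritParams adjust_continuous
#' @param outcome_col Name of the outcome column, coded 0/1 (logicals and
#'   two-level factors are converted).
#' @return A [residual_series()] of response residuals.
#' @export
adjust_binary <- function(data, outcome_col, spec,
                          time_col = "local_hours", date_col = "local_date") {
  stopifnot(inherits(spec, "adjustment_spec"))
  cr <- complete_rows(data, outcome_col, spec, time_col, date_col)
  data <- cr$data
  if (nrow(data) == 0L) stop("no rows left after missing-value filtering", call. = FALSE)
  y <- data[[outcome_col]]
  if (is.factor(y) || is.character(y)) y <- as.integer(factor(y)) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)))
    stop("binary outcome must be codable as 0/1", call. = FALSE)
  X <- build_adjustment_design(data, spec, date_col)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(), intercept = FALSE)
  )
  p <- fit$fitted.values
  if (any(p < 1e-8 | p > 1 - 1e-8)) {
    offender <- find_separating_covariate(data, y, spec)
    stop(sprintf("perfect separation in logistic adjustment (covariate '%s')",
                 offender), call. = FALSE)
  }
  out <- residual_series(y - p, data[[time_col]])
  attr(out, "n_dropped") <- cr$n_dropped
  out
}

# Identify a categorical covariate with a level in which the outcome is
# constant (the usual cause of separation); falls back to "<unknown>".
find_separating_covariate <- function(data, y, spec) {
  for (cv in spec$categorical_covariates) {
    f <- factor(data[[cv]])
    m <- tapply(y, f, mean)
    if (any(m == 0 | m == 1, na.rm = TRUE)) return(cv)
  }
  "<unknown>"
}
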
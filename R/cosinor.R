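#' Fit a single-component 24-hour cosinor by least squares
#'
#' Regresses the series on an intercept plus `sin(2*pi*t/24)` and
#' `cos(2*pi*t/24)`. The fitted rhythm is reported as mesor (midline),
#' amplitude (half the peak-to-trough distance), and acrophase (clock time of
#' the fitted peak), together with the percentage of variance explained by
#' the sine/cosine pair and the joint F test of the two trigonometric
#' coefficients. The fitted curve satisfies
#' `mesor + amplitude * cos(2*pi*(t - acrophase)/24)` identically.
#'
#' @param series A [residual_series()] (residuals from covariate adjustment,
#'   or raw outcome values when fitting unadjusted).
#' @return An object of class `"cosinor_fit"` with elements `mesor`,
#'   `beta_sin`, `beta_cos`, `amplitude`, `acrophase_hours`, `r2_pct`,
#'   `f_stat`, `df` (length 2), `p`, and `n`. For a constant series the
#'   amplitude and `r2_pct` are 0, `f_stat` is 0, and the acrophase is `NA`.
#' @export
fit_cosinor <- function(series) {
  stopifnot(inherits(series, "residual_series"))
  y <- series$residual
  t <- series$time
  n <- series$n
  if (n < 10L) stop("cosinor fitting requires at least 10 observations", call. = FALSE)
  if (length(unique(round(t, 10))) < 3L)
    stop("singular design: times must span at least 3 distinct values", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, circular_encode(t))
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  sse <- sum(fit$residuals^2)
  sst <- series$total_ss
  model_ss <- max(sst - sse, 0)
  df <- c(2, n - 3)
  if (sst <= 0) {
    # constant series: no rhythm by definition
    b[c("sin_term", "cos_term")] <- 0
    r2_pct <- 0; f_stat <- 0; p <- 1
  } else if (sse <= sst * 1e-14) {
    r2_pct <- 100; f_stat <- Inf; p <- 0
  } else {
    r2_pct <- 100 * model_ss / sst
    f_stat <- (model_ss / 2) / (sse / df[2])
    p <- stats::pf(f_stat, df[1], df[2], lower.tail = FALSE)
  }
  beta_sin <- unname(b["sin_term"]); beta_cos <- unname(b["cos_term"])
  amplitude <- sqrt(beta_sin^2 + beta_cos^2)
  acro <- if (amplitude == 0) NA_real_ else acrophase_from_coefs(beta_sin, beta_cos)
  structure(
    list(mesor = unname(b["(Intercept)"]), beta_sin = beta_sin,
         beta_cos = beta_cos, amplitude = amplitude, acrophase_hours = acro,
         r2_pct = r2_pct, f_stat = f_stat, df = df, p = p, n = n),
    class = "cosinor_fit"
  )
}

#' Acrophase (clock time of peak) from sine/cosine coefficients
#'
#' The fitted curve `beta_cos*cos(w t) + beta_sin*sin(w t)` with
#' `w = 2*pi/24` equals `A*cos(w(t - phi))` with `A = sqrt(beta_sin^2 +
#' beta_cos^2)` and `phi = (24/2pi) * atan2(beta_sin, beta_cos)`, the
#' two-argument arctangent handling all quadrants.
#'
#' @param beta_sin,beta_cos Coefficients of the sine and cosine terms.
#' @return Acrophase in decimal hours, in `[0, 24)`.
#' @export
acrophase_from_coefs <- function(beta_sin, beta_cos) {
  if (beta_sin == 0 && beta_cos == 0)
    stop("acrophase undefined: both coefficients are zero", call. = FALSE)
  wrap_hours(atan2(beta_sin, beta_cos) * 24 / (2 * pi))
}

#' Predicted rhythm values on a time grid
#'
#' @param fit A [fit_cosinor()] result.
#' @param times Clock times in decimal hours.
#' @return `mesor + amplitude * cos(2*pi*(t - acrophase)/24)` per grid point
#'   (constant `mesor` when the amplitude is zero).
#' @export
predict_curve <- function(fit, times) {
  stopifnot(inherits(fit, "cosinor_fit"))
  if (fit$amplitude == 0 || is.na(fit$acrophase_hours))
    return(rep(fit$mesor, length(times)))
  fit$mesor + fit$amplitude * cos(2 * pi * (times - fit$acrophase_hours) / 24)
}

#' Test whether a moderator shifts or rescales the 24-hour rhythm
#'
#' Adds the moderator's main effect plus two interaction terms — sine times
#' moderator and cosine times moderator — to the cosinor model, and tests the
#' interaction terms jointly with a Wald F test. A significant joint test
#' indicates that the rhythm's amplitude and/or acrophase differs across
#' moderator values. For a categorical moderator the cosinor is refit within
#' each level; for a continuous moderator the implied rhythm is evaluated at
#' reference values (by default the observed range endpoints).
#'
#' @param series A [residual_series()].
#' @param moderator Vector of per-record moderator values (same length).
#' @param kind `"categorical"` or `"continuous"`.
#' @param min_level_n For categorical moderators, levels with fewer records
#'   are dropped with a warning (default 100).
#' @param ref_values For continuous moderators, the values at which the
#'   implied rhythm is evaluated; default `range(moderator)`.
#' @return An object of class `"moderation_result"`: `joint_f`, `df`, `p`,
#'   `delta_r2_pct` (increment in percent variance explained from the
#'   interaction pair), `level_fits` (per-level [fit_cosinor()] results, or
#'   implied fits at `ref_values`), and `acrophase_shift_hours` (signed
#'   circular difference between level/reference acrophases, in `(-12, 12]`).
#' @export
moderation_test <- function(series, moderator,
                            kind = c("categorical", "continuous"),
                            min_level_n = 100, ref_values = NULL) {
  stopifnot(inherits(series, "residual_series"),
            length(moderator) == series$n)
  kind <- match.arg(kind)
  y <- series$residual
  t <- series$time
  trig <- circular_encode(t)

  if (kind == "categorical") {
    m <- factor(moderator)
    if (nlevels(m) < 2L) stop("moderator is constant", call. = FALSE)
    tab <- table(m)
    small <- names(tab)[tab < min_level_n]
    if (length(small) > 0L) {
      warning("dropping moderator level(s) below min_level_n: ",
              paste(small, collapse = ", "), call. = FALSE)
      keep <- !(m %in% small)
      y <- y[keep]; t <- t[keep]; trig <- trig[keep, , drop = FALSE]
      m <- droplevels(m[keep])
      if (nlevels(m) < 2L) stop("moderator is constant after level filtering", call. = FALSE)
    }
    D <- stats::model.matrix(~ m)[, -1L, drop = FALSE]
    X_red <- cbind(1, D, trig)
    X_full <- cbind(X_red, trig[, "sin_term"] * D, trig[, "cos_term"] * D)
    q <- 2L * ncol(D)
    levels_out <- levels(m)
    level_fits <- lapply(levels_out, function(lv) {
      fit_cosinor(residual_series(y[m == lv], t[m == lv]))
    })
    names(level_fits) <- levels_out
  } else {
    m <- as.numeric(moderator)
    if (anyNA(m)) stop("moderator contains missing values", call. = FALSE)
    if (stats::var(m) == 0) stop("moderator is constant", call. = FALSE)
    mc <- m - mean(m)
    X_red <- cbind(1, mc, trig)
    X_full <- cbind(X_red, trig[, "sin_term"] * mc, trig[, "cos_term"] * mc)
    q <- 2L
    if (is.null(ref_values)) ref_values <- range(m)
  }

  n <- length(y)
  fit_full <- stats::lm.fit(X_full, y)
  fit_red <- stats::lm.fit(X_red, y)
  sse_f <- sum(fit_full$residuals^2)
  sse_r <- sum(fit_red$residuals^2)
  df2 <- n - fit_full$rank
  sst <- sum((y - mean(y))^2)
  joint_f <- max(sse_r - sse_f, 0) / q / (sse_f / df2)
  p <- stats::pf(joint_f, q, df2, lower.tail = FALSE)
  delta_r2_pct <- if (sst > 0) 100 * max(sse_r - sse_f, 0) / sst else 0

  if (kind == "continuous") {
    b <- fit_full$coefficients
    # columns: 1, mc, sin, cos, sin*mc, cos*mc
    level_fits <- lapply(ref_values, function(v) {
      vc <- v - mean(m)
      bs <- unname(b[3] + b[5] * vc)
      bc <- unname(b[4] + b[6] * vc)
      amp <- sqrt(bs^2 + bc^2)
      structure(
        list(mesor = unname(b[1] + b[2] * vc), beta_sin = bs, beta_cos = bc,
             amplitude = amp,
             acrophase_hours = if (amp == 0) NA_real_ else acrophase_from_coefs(bs, bc),
             r2_pct = NA_real_, f_stat = NA_real_, df = c(NA_real_, NA_real_),
             p = NA_real_, n = NA_integer_),
        class = "cosinor_fit"
      )
    })
    names(level_fits) <- paste0("at_", signif(ref_values, 6))
    levels_out <- ref_values
  }

  acros <- vapply(level_fits, function(f) f$acrophase_hours, numeric(1))
  shift <- if (length(acros) == 2L) {
    circular_diff_hours(acros[2L], acros[1L])
  } else {
    stats::setNames(circular_diff_hours(acros[-1L], acros[1L]),
                    names(acros)[-1L])
  }

  structure(
    list(joint_f = joint_f, df = c(q, df2), p = p,
         delta_r2_pct = delta_r2_pct, kind = kind,
         levels = levels_out, level_fits = level_fits,
         acrophase_shift_hours = shift, n = n),
    class = "moderation_result"
  )
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat("24-h cosinor fit\n")
  cat(sprintf("  mesor %.5g  amplitude %.5g  acrophase %s (%.3f h)\n",
              x$mesor, x$amplitude,
              ifelse(is.na(x$acrophase_hours), "NA", hours_to_hhmm(x$acrophase_hours)),
              x$acrophase_hours))
  cat(sprintf("  variance explained %.4g%%  F(%g, %g) = %.4g, p = %.3g  (n = %d)\n",
              x$r2_pct, x$df[1], x$df[2], x$f_stat, x$p, x$n))
  invisible(x)
}

#' @export
print.moderation_result <- function(x, ...) {
  cat(sprintf("Rhythm moderation (%s moderator), n = %d\n", x$kind, x$n))
  cat(sprintf("  joint interaction F(%g, %g) = %.4g, p = %.3g, delta r2 = %.4g%%\n",
              x$df[1], x$df[2], x$joint_f, x$p, x$delta_r2_pct))
  acros <- vapply(x$level_fits, function(f) f$acrophase_hours, numeric(1))
  for (i in seq_along(acros)) {
    cat(sprintf("  %s: acrophase %s\n", names(x$level_fits)[i],
                ifelse(is.na(acros[i]), "NA", hours_to_hhmm(acros[i]))))
  }
  if (length(x$acrophase_shift_hours) == 1L)
    cat(sprintf("  acrophase shift: %+.2f h (%s%d min)\n",
                x$acrophase_shift_hours,
                ifelse(x$acrophase_shift_hours < 0, "-", "+"),
                abs(round(60 * x$acrophase_shift_hours))))
  invisible(x)
}

#' Flatten a cosinor fit to a one-row data.frame (for CSV reports)
#'
#' @param x A `cosinor_fit`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return One-row data.frame with mesor, coefficients, amplitude, acrophase
#'   (decimal hours and hh:mm), variance explained, F, df, p, and n.
#' @export
as.data.frame.cosinor_fit <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    mesor = x$mesor, beta_sin = x$beta_sin, beta_cos = x$beta_cos,
    amplitude = x$amplitude, acrophase_hours = x$acrophase_hours,
    acrophase_hhmm = hours_to_hhmm(x$acrophase_hours),
    r2_pct = x$r2_pct, f_stat = x$f_stat, df1 = x$df[1], df2 = x$df[2],
    p = x$p, n = x$n, stringsAsFactors = FALSE
  )
}
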
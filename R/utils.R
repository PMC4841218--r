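#' Wrap hours onto the 24-hour clock
#'
#' @param hours Numeric vector of hours (any real values).
#' @return Values wrapped into `[0, 24)`.
#' @export
wrap_hours <- function(hours) {
  hours %% 24
}

#' Signed circular difference between two clock times
#'
#' Computes `a - b` on the 24-hour circle, wrapped into the interval
#' `(-12, 12]` hours so that the shortest signed arc is reported.
#'
#' @param a,b Clock times in decimal hours.
#' @return Signed difference in hours, in `(-12, 12]`.
#' @export
circular_diff_hours <- function(a, b) {
  d <- (a - b) %% 24
  ifelse(d > 12, d - 24, d)
}

#' Format decimal hours as hh:mm clock time
#'
#' @param hours Decimal hours in `[0, 24)` (values outside are wrapped).
#' @return Character vector like `"21:10"`. `NA` stays `NA`.
#' @export
hours_to_hhmm <- function(hours) {
  out <- rep(NA_character_, length(hours))
  ok <- !is.na(hours)
  h <- wrap_hours(hours[ok])
  total_min <- round(h * 60)
  total_min <- total_min %% (24 * 60)
  out[ok] <- sprintf("%02d:%02d", total_min %/% 60, total_min %% 60)
  out
}

# Circular (weighted) mean of clock times, in [0, 24). Returns NA for empty
# input or when the resultant length is numerically zero.
circular_mean_hours <- function(hours, w = NULL) {
  if (length(hours) == 0L) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(hours))
  ang <- 2 * pi * hours / 24
  s <- sum(w * sin(ang))
  c <- sum(w * cos(ang))
  if (sqrt(s^2 + c^2) < 1e-12 * sum(w)) return(NA_real_)
  wrap_hours(atan2(s, c) * 24 / (2 * pi))
}

# Internal logger: message() with a consistent prefix, so pipeline exclusion
# counts are greppable on stderr.
log_note <- function(fmt, ...) {
  message(sprintf(paste0("[cosinorsel] ", fmt), ...))
}
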
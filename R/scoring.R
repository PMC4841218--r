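#' Recode a signed outcome score into an in-group preference score
#'
#' Raw IAT D scores for the Black-White race task are signed so that positive
#' values indicate a preference for White over Black targets. Because people
#' tend to prefer their own group, the score is harmonized across respondent
#' race: for members of the designated reverse-coded group(s) (by default,
#' Black respondents) the sign is flipped, so that positive values always
#' mean in-group preference.
#'
#' @param d_raw Numeric vector of raw signed scores.
#' @param race Character/factor vector of race labels, same length.
#' @param reverse_groups Character vector of race labels whose scores are
#'   sign-flipped. Defaults to `"Black"` plus the older `"Black-not Hispanic"`
#'   label used by earlier versions of the race item.
#' @return Numeric vector of in-group-coded scores. Elements with missing
#'   `race` are returned as `NA` (such records are excluded from analysis,
#'   which requires race).
#' @export
recode_ingroup <- function(d_raw, race,
                           reverse_groups = c("Black", "Black-not Hispanic")) {
  stopifnot(length(d_raw) == length(race))
  race <- as.character(race)
  out <- ifelse(race %in% reverse_groups, -d_raw, d_raw)
  out[is.na(race)] <- NA_real_
  out
}
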
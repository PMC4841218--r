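#' Configuration for a full pipeline run
#'
#' Exactly one of `input` (a CSV of participant records) or `preset` (a
#' [scenario_preset()] name, simulated at `n`/`seed`) must be supplied.
#'
#' @param input Path to a records CSV, or `NULL`.
#' @param preset Simulation preset name, or `NULL`.
#' @param n,seed Simulation size and seed (used with `preset`; `seed` also
#'   recorded for provenance).
#' @param column_mapping Optional named character vector mapping the standard
#'   column names (`timestamp`, `region_id`, `age`, `gender`, `race`,
#'   `d_raw`) to the file's column names.
#' @param zone_table As [default_zone_table()]; or build one from CSVs with
#'   [read_zone_table()] and supply `list(zones = ..., server = ...)`.
#' @param covariates Demographic columns treated as categorical in the
#'   adjusted model (age is expanded to one indicator per year).
#' @param detrend Include linear + quadratic study-day terms.
#' @param age_range_full,age_range_young Age windows for the stratified
#'   acrophase curve and the continuous-age sensitivity analysis.
#' @param stratum_min_n Minimum records per age stratum.
#' @param min_level_n Minimum records per moderator level.
#' @param reverse_groups Race labels whose raw scores are sign-flipped (see
#'   [recode_ingroup()]).
#' @param out_dir Output directory for the JSON report, CSV exports, and log;
#'   `NULL` writes nothing.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(input = NULL, preset = NULL, n = 10000, seed = 1,
                       column_mapping = NULL,
                       zone_table = default_zone_table(),
                       covariates = c("age", "gender", "race"),
                       detrend = TRUE,
                       age_range_full = c(18, 89),
                       age_range_young = c(18, 40),
                       stratum_min_n = 50,
                       min_level_n = 100,
                       reverse_groups = c("Black", "Black-not Hispanic"),
                       out_dir = NULL) {
  if (is.null(input) == is.null(preset))
    stop("exactly one of 'input' or 'preset' must be set", call. = FALSE)
  structure(
    list(input = input, preset = preset, n = n, seed = seed,
         column_mapping = column_mapping, zone_table = zone_table,
         covariates = covariates, detrend = detrend,
         age_range_full = age_range_full, age_range_young = age_range_young,
         stratum_min_n = stratum_min_n, min_level_n = min_level_n,
         reverse_groups = reverse_groups, out_dir = out_dir),
    class = "run_config"
  )
}

#' Read participant records from a delimited file
#'
#' @param path CSV path (header required).
#' @param column_mapping Optional named character vector mapping standard
#'   names to the file's column names; names not present in the file are an
#'   error.
#' @return Data.frame with the standard columns `timestamp`, `region_id`,
#'   `age`, `gender`, `race`, `d_raw`. Rows with an unparseable timestamp or
#'   age are dropped with a logged count.
#' @export
read_records <- function(path, column_mapping = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("input file has no data rows: ", path, call. = FALSE)
  std <- c("timestamp", "region_id", "age", "gender", "race", "d_raw")
  if (!is.null(column_mapping)) {
    bad <- setdiff(unname(column_mapping), names(df))
    if (length(bad) > 0L)
      stop("column_mapping refers to unknown column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    for (s in names(column_mapping)) names(df)[names(df) == column_mapping[[s]]] <- s
  }
  missing_cols <- setdiff(std, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  ts_ok <- !is.na(suppressWarnings(parse_ts(df$timestamp)))
  age_num <- suppressWarnings(as.numeric(df$age))
  age_ok <- !is.na(age_num)
  keep <- ts_ok & age_ok
  if (any(!keep))
    log_note("dropped %d record(s) with unparseable timestamp or age", sum(!keep))
  df <- df[keep, std, drop = FALSE]
  df$age <- as.integer(round(age_num[keep]))
  df$d_raw <- as.numeric(df$d_raw)
  attr(df, "n_dropped_parse") <- sum(!keep)
  df
}

# One-row data.frame summary of a moderation result (for CSV export).
moderation_row <- function(mr, label) {
  shift <- if (length(mr$acrophase_shift_hours) == 1L)
    unname(mr$acrophase_shift_hours) else NA_real_
  data.frame(
    moderator = label, joint_f = mr$joint_f, df1 = mr$df[1], df2 = mr$df[2],
    p = mr$p, delta_r2_pct = mr$delta_r2_pct,
    acrophase_shift_hours = shift,
    acrophase_shift_min = shift * 60, n = mr$n,
    stringsAsFactors = FALSE
  )
}

# Observed outcome means in half-hour clock-time bins (reporting only).
binned_means <- function(hours, values, bin_width_h = 0.5) {
  bin <- floor(hours / bin_width_h)
  agg <- stats::aggregate(values, by = list(bin = bin),
                          FUN = function(v) c(mean = mean(v), n = length(v)))
  data.frame(bin_start_hours = agg$bin * bin_width_h,
             mean = agg$x[, "mean"], n = agg$x[, "n"])
}

#' Run the full rhythm-versus-selection pipeline
#'
#' Executes, in order: load or simulate records; convert server timestamps to
#' local clock time; exclude DST transition days; recode the raw score to
#' in-group preference; fit the demographics-adjusted and
#' detrended-but-unadjusted cosinors (stage 1); test moderation of the
#' adjusted rhythm by DST status, gender, and age — the latter both as a
#' per-age-year acrophase curve with its weighted linear summary and as a
#' continuous-age sensitivity model (stage 2); and fit cosinor benchmarks to
#' age and gender themselves, forming variance-explained ratios against the
#' outcome (stage 3). Every exclusion is counted in the returned `meta`
#' block and logged.
#'
#' @param config A [run_config()].
#' @return A report list with elements `meta`, `part1`, `part2`, `part3`, and
#'   `binned_means`; written as JSON + CSVs + a log file when
#'   `config$out_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  zt <- config$zone_table

  records <- if (!is.null(config$input)) {
    read_records(config$input, config$column_mapping)
  } else {
    simulate_participants(scenario_preset(config$preset, n = config$n,
                                          seed = config$seed))
  }
  n_input <- nrow(records)
  n_parse <- attr(records, "n_dropped_parse")
  if (is.null(n_parse)) n_parse <- 0L

  records <- localize_records(records, zt$zones, server_zone = zt$server)
  n_zone <- attr(records, "n_dropped_zone")

  records <- exclude_transition_days(records, zt$zones)
  n_dst_days <- attr(records, "n_excluded")

  records$d_ingroup <- recode_ingroup(records$d_raw, records$race,
                                      config$reverse_groups)
  need <- unique(c("d_ingroup", config$covariates, "age", "gender", "dst",
                   "local_hours", "local_date"))
  need <- intersect(need, names(records))
  ok <- stats::complete.cases(records[, need, drop = FALSE])
  n_missing <- sum(!ok)
  if (n_missing > 0L)
    log_note("dropped %d record(s) with missing analysis fields", n_missing)
  records <- records[ok, , drop = FALSE]
  if (nrow(records) == 0L) stop("no records left for analysis", call. = FALSE)
  records$is_female <- as.integer(records$gender == "female")

  # Stage 1: adjusted and unadjusted rhythm
  spec_adj <- adjustment_spec(config$covariates, detrend = config$detrend)
  spec_unadj <- adjustment_spec(character(0), detrend = config$detrend)
  series_adj <- adjust_continuous(records, "d_ingroup", spec_adj)
  series_unadj <- adjust_continuous(records, "d_ingroup", spec_unadj)
  fit_adj <- fit_cosinor(series_adj)
  fit_unadj <- fit_cosinor(series_unadj)

  # Stage 2: moderation by DST, gender, and age
  mod_dst <- moderation_test(series_adj, records$dst, "categorical",
                             min_level_n = config$min_level_n)
  mod_gender <- moderation_test(series_adj, records$gender, "categorical",
                                min_level_n = config$min_level_n)
  curve <- weighted_acrophase_regression(
    acrophase_by_stratum(series_adj, records$age,
                         age_range = config$age_range_full,
                         min_n = config$stratum_min_n)
  )
  mod_age <- continuous_age_moderation(series_adj, records$age,
                                       age_range = config$age_range_young)

  # Stage 3: fixed-variable benchmarks
  cov_no_age <- setdiff(config$covariates, "age")
  cov_no_gender <- setdiff(config$covariates, "gender")
  bm_age <- benchmark_fixed_variable(
    records, "age", "continuous",
    adjustment_spec(cov_no_age, detrend = config$detrend))
  bm_gender <- benchmark_fixed_variable(
    records, "is_female", "binary",
    adjustment_spec(cov_no_gender, detrend = config$detrend,
                    outcome_kind = "binary"))
  ratios <- benchmark_ratios(fit_adj$r2_pct,
                             list(age = bm_age, gender = bm_gender))

  report <- list(
    meta = list(
      preset = config$preset, input = config$input, seed = config$seed,
      n_input = n_input,
      exclusions = list(unparseable = n_parse, unknown_zone = n_zone,
                        dst_transition_days = n_dst_days,
                        missing_fields = n_missing),
      n_analyzed = nrow(records)
    ),
    part1 = list(adjusted = as.data.frame(fit_adj),
                 unadjusted = as.data.frame(fit_unadj)),
    part2 = list(
      dst = moderation_row(mod_dst, "dst"),
      gender = moderation_row(mod_gender, "gender"),
      age_curve = curve$strata,
      age_curve_fit = data.frame(slope_min_per_year = curve$slope_min_per_year,
                                 intercept_hours = curve$intercept_hours,
                                 weighted_r2_pct = curve$weighted_r2_pct),
      age_continuous = c(
        moderation_row(mod_age, "age_continuous"),
        list(endpoint_shift_min = 60 * mod_age$endpoint_shift_hours)
      )
    ),
    part3 = list(
      r2_outcome_pct = ratios$r2_outcome_pct,
      benchmarks = ratios$benchmarks,
      outcome_r2_zero = ratios$outcome_r2_zero
    ),
    binned_means = binned_means(records$local_hours, records$d_ingroup),
    objects = list(fit_adjusted = fit_adj, fit_unadjusted = fit_unadj,
                   moderation_dst = mod_dst, moderation_gender = mod_gender,
                   acrophase_curve = curve, moderation_age = mod_age,
                   benchmark = ratios)
  )

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Serialize a pipeline report: JSON + per-model CSVs + plain-text log.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- report[c("meta", "part1", "part2", "part3", "binned_means")]
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(rbind(cbind(model = "adjusted", report$part1$adjusted),
                         cbind(model = "unadjusted", report$part1$unadjusted)),
                   file.path(out_dir, "part1_fits.csv"), row.names = FALSE)
  utils::write.csv(rbind(report$part2$dst, report$part2$gender),
                   file.path(out_dir, "part2_moderation.csv"), row.names = FALSE)
  curve <- report$part2$age_curve
  curve$acrophase_hhmm <- hours_to_hhmm(curve$acrophase_hours)
  utils::write.csv(curve, file.path(out_dir, "acrophase_by_age.csv"),
                   row.names = FALSE)
  utils::write.csv(report$part3$benchmarks,
                   file.path(out_dir, "part3_benchmarks.csv"), row.names = FALSE)
  utils::write.csv(report$binned_means,
                   file.path(out_dir, "binned_means.csv"), row.names = FALSE)
  ex <- report$meta$exclusions
  log_lines <- c(
    sprintf("records in: %d", report$meta$n_input),
    sprintf("excluded unparseable: %d", ex$unparseable),
    sprintf("excluded unknown zone: %d", ex$unknown_zone),
    sprintf("excluded DST transition days: %d", ex$dst_transition_days),
    sprintf("excluded missing fields: %d", ex$missing_fields),
    sprintf("records analyzed: %d", report$meta$n_analyzed)
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(NULL)
}
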
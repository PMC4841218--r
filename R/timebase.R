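#' Timezone specification for a study region
#'
#' A zone is described by its clock offset from the server zone and, if it
#' observes daylight saving time (DST), by an explicit table of DST intervals.
#' DST rules are supplied as data rather than taken from the operating
#' system's timezone database, so analyses are reproducible across machines
#' and historical rules can be encoded exactly. Counties straddling two
#' timezones are represented with a half-integer offset (e.g. `-0.5`), coding
#' them half-way between the two zones.
#'
#' @param offset_hours Signed offset in hours from the server zone's standard
#'   time, in `[-12, 12]`; half-integer values are permitted.
#' @param observes_dst Logical; does this zone shift its clocks for DST?
#' @param dst_intervals `NULL`, or a data.frame with columns `start` and `end`
#'   (`POSIXct` or ISO-8601 strings, interpreted as this zone's standard
#'   time), one row per DST period, non-overlapping and ordered.
#' @return An object of class `"zone_spec"`.
#' @export
zone_spec <- function(offset_hours, observes_dst = FALSE, dst_intervals = NULL) {
  stopifnot(is.numeric(offset_hours), length(offset_hours) == 1L, !is.na(offset_hours))
  if (offset_hours < -12 || offset_hours > 12)
    stop("offset_hours must lie in [-12, 12]", call. = FALSE)
  if (observes_dst) {
    if (is.null(dst_intervals) || nrow(dst_intervals) == 0L)
      stop("a zone with observes_dst = TRUE needs at least one DST interval", call. = FALSE)
    dst_intervals <- data.frame(
      start = parse_ts(dst_intervals$start),
      end   = parse_ts(dst_intervals$end)
    )
    if (any(is.na(dst_intervals$start)) || any(is.na(dst_intervals$end)))
      stop("unparseable DST interval date-times", call. = FALSE)
    if (any(dst_intervals$end <= dst_intervals$start))
      stop("DST intervals must have end > start", call. = FALSE)
    o <- order(dst_intervals$start)
    dst_intervals <- dst_intervals[o, , drop = FALSE]
    if (nrow(dst_intervals) > 1L &&
        any(dst_intervals$start[-1L] < dst_intervals$end[-nrow(dst_intervals)]))
      stop("DST intervals must be non-overlapping", call. = FALSE)
  } else {
    dst_intervals <- NULL
  }
  structure(
    list(offset_hours = offset_hours, observes_dst = observes_dst,
         dst_intervals = dst_intervals),
    class = "zone_spec"
  )
}

# Parse timestamps on a fixed calendar ("UTC" is used as a plain clock
# container; no OS timezone rules are consulted). Unparseable elements come
# back NA rather than aborting the whole vector.
parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  x <- as.character(x)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%OS", tz = "UTC"), tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- which(is.na(out) & !is.na(x))
    if (length(miss) == 0L) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"), tz = "UTC")
  }
  out
}

# Is each (standard-time) instant inside one of the zone's DST intervals?
in_dst <- function(zone, when) {
  if (!zone$observes_dst) return(rep(FALSE, length(when)))
  iv <- zone$dst_intervals
  res <- rep(FALSE, length(when))
  for (i in seq_len(nrow(iv))) {
    res <- res | (when >= iv$start[i] & when < iv$end[i])
  }
  res
}

# Calendar dates on which a zone's clocks transition (DST start or end days).
transition_dates <- function(zone) {
  if (!zone$observes_dst) return(as.Date(character(0)))
  as.Date(c(format(zone$dst_intervals$start, "%Y-%m-%d"),
            format(zone$dst_intervals$end, "%Y-%m-%d")))
}

#' Convert a server-clock timestamp to local clock time
#'
#' Local time is `server clock + offset + DST correction`, wrapped modulo 24
#' with the calendar date rolled accordingly. The DST correction is +1 hour
#' while the local zone is on DST and -1 hour while the server zone is (the
#' two cancel where both observe DST over the same dates, the usual case).
#'
#' @param server_timestamp Server-clock date-times (`POSIXct` or parseable
#'   strings).
#' @param zone A [zone_spec()] for the record's region.
#' @param server_zone Optional [zone_spec()] describing the server's own DST
#'   behaviour; `NULL` means no server-side correction.
#' @return A data.frame with columns `local_hours` (decimal hours in
#'   `[0, 24)`), `local_date` (`Date`), and `dst` (logical; local zone on DST).
#' @export
to_local_time <- function(server_timestamp, zone, server_zone = NULL) {
  stopifnot(inherits(zone, "zone_spec"))
  ts <- parse_ts(server_timestamp)
  if (any(is.na(ts))) {
    stop(sprintf("unparseable timestamp at row(s): %s",
                 paste(which(is.na(ts)), collapse = ", ")), call. = FALSE)
  }
  server_dst <- if (is.null(server_zone)) rep(FALSE, length(ts)) else in_dst(server_zone, ts)
  server_standard <- ts - 3600 * server_dst
  local_standard <- server_standard + 3600 * zone$offset_hours
  local_dst <- in_dst(zone, local_standard)
  local_wall <- local_standard + 3600 * local_dst
  # POSIXct here lives on a fixed UTC-like calendar, so clock time and date
  # fall out of integer arithmetic on the epoch seconds
  secs <- as.numeric(local_wall)
  hrs <- (secs %% 86400) / 3600
  data.frame(
    local_hours = wrap_hours(hrs),
    local_date = as.Date(floor(secs / 86400), origin = "1970-01-01"),
    dst = local_dst
  )
}

#' Drop records that fall on a DST transition day
#'
#' Records whose local calendar date coincides with a clock change (DST start
#' or end) in their zone are removed; records in zones that never observe DST
#' are always retained. Order is preserved. The operation is idempotent.
#'
#' @param records A data.frame with columns `local_date` and a region
#'   identifier column.
#' @param zones Named list of [zone_spec()] objects, keyed by region id.
#' @param region_col Name of the region identifier column.
#' @return The filtered data.frame, with an attribute `n_excluded` giving the
#'   number of rows removed.
#' @export
exclude_transition_days <- function(records, zones, region_col = "region_id") {
  stopifnot(is.data.frame(records), "local_date" %in% names(records),
            region_col %in% names(records))
  if (nrow(records) == 0L) {
    attr(records, "n_excluded") <- 0L
    return(records)
  }
  drop <- rep(FALSE, nrow(records))
  for (rid in unique(as.character(records[[region_col]]))) {
    zone <- zones[[rid]]
    if (is.null(zone)) next
    td <- transition_dates(zone)
    if (length(td) == 0L) next
    sel <- records[[region_col]] == rid
    drop[sel] <- records$local_date[sel] %in% td
  }
  out <- records[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Sine/cosine encoding of clock time with 24-hour periodicity
#'
#' @param t Clock time(s) in decimal hours.
#' @return A matrix with columns `sin_term` and `cos_term`, i.e.
#'   `sin(2*pi*t/24)` and `cos(2*pi*t/24)`; each row has unit sum of squares.
#' @export
circular_encode <- function(t) {
  ang <- 2 * pi * t / 24
  cbind(sin_term = sin(ang), cos_term = cos(ang))
}

#' Read a zone table (and optional DST interval table) from CSV
#'
#' @param zone_csv Path to a CSV with columns `region_id`, `offset_hours`,
#'   `observes_dst`.
#' @param dst_csv Optional path to a CSV with columns `region_id`,
#'   `dst_start`, `dst_end` (ISO-8601 date-times in the zone's standard time).
#' @return Named list of [zone_spec()] objects keyed by `region_id`.
#' @export
read_zone_table <- function(zone_csv, dst_csv = NULL) {
  zt <- utils::read.csv(zone_csv, stringsAsFactors = FALSE)
  need <- c("region_id", "offset_hours", "observes_dst")
  if (!all(need %in% names(zt)))
    stop("zone table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  dst <- if (!is.null(dst_csv)) utils::read.csv(dst_csv, stringsAsFactors = FALSE) else NULL
  zones <- list()
  for (i in seq_len(nrow(zt))) {
    rid <- as.character(zt$region_id[i])
    obs <- as.logical(zt$observes_dst[i])
    iv <- NULL
    if (obs && !is.null(dst)) {
      sub <- dst[as.character(dst$region_id) == rid, , drop = FALSE]
      if (nrow(sub) > 0L) iv <- data.frame(start = sub$dst_start, end = sub$dst_end)
    }
    zones[[rid]] <- zone_spec(zt$offset_hours[i], obs, iv)
  }
  zones
}

#' Attach local clock time to a table of participant records
#'
#' Vectorized wrapper around [to_local_time()]: records are grouped by region,
#' converted, and returned with `local_hours`, `local_date`, and `dst`
#' columns. Records with a missing or unknown region, or an unparseable
#' timestamp, are dropped with a logged count (the study design requires a
#' known local timezone).
#'
#' @param records Data.frame with a timestamp column and a region id column.
#' @param zones Named list of [zone_spec()]s.
#' @param server_zone Optional server [zone_spec()] (see [to_local_time()]).
#' @param timestamp_col,region_col Column names.
#' @return `records` plus the three local-time columns; attribute
#'   `n_dropped_zone` counts removed rows.
#' @export
localize_records <- function(records, zones, server_zone = NULL,
                             timestamp_col = "timestamp",
                             region_col = "region_id") {
  stopifnot(timestamp_col %in% names(records), region_col %in% names(records))
  rid <- as.character(records[[region_col]])
  known <- !is.na(rid) & rid %in% names(zones)
  ts <- parse_ts(records[[timestamp_col]])
  ok <- known & !is.na(ts)
  n_drop <- sum(!ok)
  if (n_drop > 0L)
    log_note("dropped %d record(s) with missing/unknown region or unparseable timestamp", n_drop)
  records <- records[ok, , drop = FALSE]
  rid <- rid[ok]
  ts <- ts[ok]
  local_hours <- numeric(nrow(records))
  local_date <- as.Date(rep(NA, nrow(records)))
  dst <- logical(nrow(records))
  for (r in unique(rid)) {
    sel <- rid == r
    lt <- to_local_time(ts[sel], zones[[r]], server_zone)
    local_hours[sel] <- lt$local_hours
    local_date[sel] <- lt$local_date
    dst[sel] <- lt$dst
  }
  records$local_hours <- local_hours
  records$local_date <- local_date
  records$dst <- dst
  attr(records, "n_dropped_zone") <- n_drop
  records
}
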
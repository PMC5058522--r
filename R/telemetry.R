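#' Read and write GPS telemetry CSV
#'
#' Schema: `animal_id`, `timestamp` (ISO-8601, read as UTC unless an offset
#' is embedded), `x`, `y` (projected meters), `dop`; extra columns (e.g.
#' `herd`) are carried through. Malformed rows (unparseable timestamp,
#' non-finite coordinates, negative DOP) are skipped with a message giving
#' the count.
#'
#' @param path CSV file path.
#' @return data.frame of fixes ordered by animal and time.
#' @export
read_telemetry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "x", "y", "dop")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("telemetry CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  # per-element format cascade; unparseable stamps stay NA and are skipped
  ts <- as.POSIXct(rep(NA_real_, nrow(df)), origin = "1970-01-01",
                   tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    need <- is.na(ts)
    if (!any(need)) break
    ts[need] <- as.POSIXct(strptime(df$timestamp[need], fmt, tz = "UTC"))
  }
  bad <- is.na(ts) | !is.finite(df$x) | !is.finite(df$y) |
    is.na(df$dop) | df$dop < 0
  if (any(bad))
    message("read_telemetry: skipped ", sum(bad), " malformed row(s)")
  df <- df[!bad, , drop = FALSE]
  df$timestamp <- ts[!bad]
  df <- df[order(df$animal_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_telemetry
#' @param fixes data.frame of fixes.
#' @export
write_telemetry <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter fixes by dilution of precision
#'
#' Retains exactly the fixes whose DOP is strictly below `max_dop` (a fix
#' with DOP equal to the threshold is discarded), preserving order. The
#' conventional screening threshold is 10.
#'
#' @param fixes data.frame with a `dop` column (>= 0).
#' @param max_dop strict upper bound (default 10).
#' @return the retained rows of `fixes`.
#' @export
filter_by_dop <- function(fixes, max_dop = 10) {
  if (!"dop" %in% names(fixes))
    stop("fixes must have a 'dop' column", call. = FALSE)
  if (any(is.na(fixes$dop)) || any(fixes$dop < 0))
    stop("negative or missing DOP values are invalid", call. = FALSE)
  fixes[fixes$dop < max_dop, , drop = FALSE]
}

#' Daily movement rate series for one individual
#'
#' For each calendar date `d` (UTC), sums the Euclidean lengths of the steps
#' between consecutive fixes whose *later* fix falls on `d`, divides by the
#' total time those steps span, and reports the result in km/day. Days in
#' the deployment range with no step ending on them are flagged uncovered
#' (`rate = NA`). The rate is invariant under rigid translation of the
#' coordinates, and `sum(rate * span_days)` over covered days reconstructs
#' the total path length.
#'
#' @param track data.frame of fixes for a single animal, time-ordered.
#' @return data.frame with one row per date: `date`, `rate` (km/day),
#'   `span_days` (time spanned by the day's steps), `n_steps`, `covered`.
#' @export
daily_movement_rate <- function(track) {
  if (length(unique(track$animal_id)) > 1)
    stop("daily_movement_rate() expects a single individual", call. = FALSE)
  n <- nrow(track)
  dates <- as.Date(track$timestamp, tz = "UTC")
  all_days <- if (n) seq(min(dates), max(dates), by = "day") else
    as.Date(character())
  empty <- data.frame(date = all_days, rate = NA_real_, span_days = NA_real_,
                      n_steps = 0L, covered = FALSE)
  if (n < 2) return(empty)
  if (is.unsorted(as.numeric(track$timestamp), strictly = TRUE))
    stop("track timestamps must be strictly increasing", call. = FALSE)
  len_km <- sqrt(diff(track$x)^2 + diff(track$y)^2) / 1000
  dt_day <- diff(as.numeric(track$timestamp)) / 86400
  end_date <- dates[-1]
  agg_len <- tapply(len_km, end_date, sum)
  agg_dt <- tapply(dt_day, end_date, sum)
  agg_n <- tapply(len_km, end_date, length)
  idx <- match(names(agg_len), as.character(all_days))
  out <- empty
  out$rate[idx] <- as.numeric(agg_len) / as.numeric(agg_dt)
  out$span_days[idx] <- as.numeric(agg_dt)
  out$n_steps[idx] <- as.integer(agg_n)
  out$covered[idx] <- TRUE
  out
}

#' Clip a track to a season window
#'
#' Keeps fixes with `start <= t < end` (half-open, so consecutive seasons
#' never double-count a fix) and reports whether the clipped track spans the
#' whole window: first fix within `tolerance_days` of the start and last fix
#' within `tolerance_days` of the end. Individuals whose collars failed
#' mid-season are thereby flagged incomplete and can be excluded downstream.
#'
#' @param track data.frame of fixes for one individual.
#' @param start,end POSIXct (or coercible) window bounds.
#' @param tolerance_days slack (days) allowed at each end (default 1).
#' @return list with `track` (the clipped fixes) and `complete` (logical).
#' @export
clip_to_season <- function(track, start, end, tolerance_days = 1) {
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (end <= start) stop("season window must have end > start", call. = FALSE)
  inside <- track$timestamp >= start & track$timestamp < end
  clipped <- track[inside, , drop = FALSE]
  tol <- tolerance_days * 86400
  complete <- nrow(clipped) > 0 &&
    as.numeric(min(clipped$timestamp)) <= as.numeric(start) + tol &&
    as.numeric(max(clipped$timestamp)) >= as.numeric(end) - tol
  list(track = clipped, complete = complete)
}

#' Split fixes into per-individual tracks
#'
#' @param fixes data.frame of fixes (any number of individuals).
#' @return named list of single-individual data.frames, time-ordered.
#' @export
split_tracks <- function(fixes) {
  fixes <- fixes[order(fixes$animal_id, fixes$timestamp), , drop = FALSE]
  split(fixes, fixes$animal_id)
}
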
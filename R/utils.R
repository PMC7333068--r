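# Shared time helpers. All timestamps are stored as POSIXct in UTC; a
# participant-local clock is recovered by adding the tz_offset carried in the
# input files ("+HH:MM" / "-HH:MM"). Day indices count whole local calendar
# days since the treatment start date (day 0 = install/baseline day).

TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

parse_ts <- function(x) {
  as.POSIXct(x, format = TS_FORMAT, tz = "UTC")
}

fmt_ts <- function(t) {
  format(t, TS_FORMAT, tz = "UTC")
}

#' Parse a timezone offset string to seconds
#'
#' @param x character vector of offsets of the form `"+HH:MM"` or `"-HH:MM"`.
#' @return numeric vector of offsets in seconds.
#' @examples
#' parse_tz_offset(c("+00:00", "-05:00", "+01:30"))
#' @export
parse_tz_offset <- function(x) {
  m <- regexec("^([+-])(\\d{2}):(\\d{2})$", x)
  parts <- regmatches(x, m)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("invalid tz_offset value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  sgn <- ifelse(vapply(parts, `[`, "", 2L) == "-", -1, 1)
  hh <- as.numeric(vapply(parts, `[`, "", 3L))
  mm <- as.numeric(vapply(parts, `[`, "", 4L))
  sgn * (hh * 3600 + mm * 60)
}

treatment_origin <- function(treatment_start) {
  as.POSIXct(paste(format(as.Date(treatment_start)), "00:00:00"), tz = "UTC")
}

# Minutes elapsed on the participant-local clock since local midnight of the
# treatment start date.
local_study_minute <- function(t, tz_offset, treatment_start) {
  org <- treatment_origin(treatment_start)
  (as.numeric(t) + parse_tz_offset(tz_offset) - as.numeric(org)) / 60
}

# Local calendar day index since treatment start (day 0 = start date).
local_day_index <- function(t, tz_offset, treatment_start) {
  as.integer(floor(local_study_minute(t, tz_offset, treatment_start) / 1440))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Total overlap, in minutes, between intervals [s, e] (numeric minutes) and a
# single query interval [ws, we].
interval_overlap_min <- function(s, e, ws, we) {
  pmax(0, pmin(e, we) - pmax(s, ws))
}
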
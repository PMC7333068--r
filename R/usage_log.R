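# App-usage event logs and sessionization.
#
# A raw usage event is one uninterrupted on-app interval. Participants often
# use a therapy app in bursts: several brief usages separated by short breaks.
# Events separated by less than a gap threshold (default 60 min) are merged
# into a single session whose duration is *active* time — the sum of event
# durations, excluding the breaks — so two 10-min usages with a 5-min break
# count as one 20-min session.

usage_cols <- c("participant_id", "start", "end", "tz_offset")

empty_events <- function() {
  tibble::tibble(
    participant_id = character(),
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    tz_offset = character()
  )
}

empty_sessions <- function() {
  tibble::tibble(
    participant_id = character(),
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    active_minutes = numeric(),
    n_events = integer(),
    tz_offset = character()
  )
}

#' Read an app-usage event log
#'
#' Reads the comma-separated usage-log dialect
#' (`participant_id,start,end,tz_offset`, ISO-8601 UTC timestamps). Events are
#' returned sorted by participant then start time. Rows with malformed
#' timestamps, `end <= start`, or overlapping events within a participant are
#' input errors and raise informative conditions naming the offending line.
#'
#' @param path path to a usage-log CSV file.
#' @return a tibble of usage events with columns `participant_id`, `start`,
#'   `end` (POSIXct, UTC) and `tz_offset`.
#' @seealso [write_usage_log()], [merge_into_sessions()]
#' @export
read_usage_log <- function(path) {
  if (!file.exists(path)) stop("usage log not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("participant_id", "start", "end")
  if (!all(need %in% names(raw))) {
    stop("usage log must have header columns ",
         paste(need, collapse = ","), call. = FALSE)
  }
  if (!"tz_offset" %in% names(raw)) raw$tz_offset <- "+00:00"
  if (nrow(raw) == 0L) return(empty_events())

  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  start <- parse_ts(raw$start)
  end <- parse_ts(raw$end)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("malformed timestamp in usage log at line ", bad[1L] + 1L,
         call. = FALSE)
  }
  parse_tz_offset(raw$tz_offset)  # validates; errors on bad values
  neg <- which(as.numeric(end) <= as.numeric(start))
  if (length(neg)) {
    stop("event end <= start in usage log at line ", line[neg[1L]],
         call. = FALSE)
  }

  ev <- tibble::tibble(
    participant_id = raw$participant_id,
    start = start, end = end, tz_offset = raw$tz_offset
  )
  ev <- ev[order(ev$participant_id, ev$start, ev$end), , drop = FALSE]
  check_no_overlap(ev)
  ev
}

check_no_overlap <- function(ev) {
  if (nrow(ev) < 2L) return(invisible(ev))
  same <- ev$participant_id[-1L] == ev$participant_id[-nrow(ev)]
  ov <- which(same & as.numeric(ev$start[-1L]) < as.numeric(ev$end[-nrow(ev)]))
  if (length(ov)) {
    i <- ov[1L]
    stop("overlapping events for participant ", ev$participant_id[i], ": [",
         fmt_ts(ev$start[i]), ", ", fmt_ts(ev$end[i]), "] overlaps [",
         fmt_ts(ev$start[i + 1L]), ", ", fmt_ts(ev$end[i + 1L]), "]",
         call. = FALSE)
  }
  invisible(ev)
}

#' Write an app-usage event log
#'
#' Emits the identical dialect that [read_usage_log()] reads, so a write/read
#' round trip reproduces the events.
#'
#' @param events a tibble of usage events.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_usage_log <- function(events, path) {
  out <- tibble::tibble(
    participant_id = events$participant_id,
    start = fmt_ts(events$start),
    end = fmt_ts(events$end),
    tz_offset = events$tz_offset
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Merge bursty usage events into sessions
#'
#' Consecutive events of one participant whose break (end of one to start of
#' the next) is strictly less than `gap_threshold_min` are summed into a
#' single session. A session's `active_minutes` is the sum of its constituent
#' event durations — breaks are excluded — so two 10-min usages with a 5-min
#' break yield one 20-min session.
#'
#' @param events tibble of usage events, sorted by participant then start,
#'   non-overlapping within participant.
#' @param gap_threshold_min merge threshold in minutes (default 60); breaks
#'   `>=` the threshold start a new session.
#' @return tibble of sessions with columns `participant_id`, `start`, `end`,
#'   `active_minutes`, `n_events`, `tz_offset`.
#' @export
merge_into_sessions <- function(events, gap_threshold_min = 60) {
  if (!is.numeric(gap_threshold_min) || gap_threshold_min <= 0) {
    stop("gap_threshold_min must be > 0", call. = FALSE)
  }
  if (nrow(events) == 0L) return(empty_sessions())

  ord <- order(events$participant_id, events$start)
  if (!identical(ord, seq_len(nrow(events)))) {
    stop("events must be sorted by participant then start time", call. = FALSE)
  }
  check_no_overlap(events)

  n <- nrow(events)
  pid <- events$participant_id
  gap_min <- c(Inf, (as.numeric(events$start[-1L]) -
                       as.numeric(events$end[-n])) / 60)
  new_pid <- c(TRUE, pid[-1L] != pid[-n])
  grp <- cumsum(new_pid | gap_min >= gap_threshold_min)

  dur <- (as.numeric(events$end) - as.numeric(events$start)) / 60
  first <- !duplicated(grp)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble::tibble(
    participant_id = pid[first],
    start = events$start[first],
    end = events$end[last],
    active_minutes = as.vector(rowsum(dur, grp, reorder = FALSE)),
    n_events = rle(grp)$lengths,
    tz_offset = events$tz_offset[first]
  )
}

#' Remove outlying long sessions
#'
#' Sessions whose active duration strictly exceeds `max_active_min` are
#' removed (the study's a-priori cutoff of approximately 60 min) and returned
#' separately for audit; a session of exactly the cutoff is kept.
#'
#' @param sessions tibble of sessions from [merge_into_sessions()].
#' @param max_active_min cutoff in active minutes (default 60).
#' @return a list with tibbles `kept` and `removed`, input order preserved.
#' @export
filter_outlier_sessions <- function(sessions, max_active_min = 60) {
  if (!is.numeric(max_active_min) || max_active_min < 0) {
    stop("max_active_min must be >= 0", call. = FALSE)
  }
  drop <- sessions$active_minutes > max_active_min
  if (length(drop) == 0L) drop <- logical(0)
  list(kept = sessions[!drop, , drop = FALSE],
       removed = sessions[drop, , drop = FALSE])
}
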
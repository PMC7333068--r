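# Per-participant engagement features over treatment windows.
#
# Quantity of use is total session active minutes; frequency of use is the
# mean break between consecutive sessions (end-to-start), analyzed on the
# natural-log scale because the raw gaps are heavy-tailed. Windows are
# half-open day-index intervals [start_day, end_day) counted in participant-
# local calendar days from treatment start; a session belongs to a window if
# its start falls inside it.

#' Define a treatment window
#'
#' @param label `"full"` (days 0 to `treatment_days`), `"first_half"` (days 0
#'   to `treatment_days / 2`), or `"custom"` with explicit bounds.
#' @param start_day,end_day day-index bounds for a custom window; the window
#'   is the half-open interval `[start_day, end_day)`.
#' @param treatment_days length of the full treatment in days (default 84,
#'   i.e. 12 weeks).
#' @return a `treatment_window` list with `label`, `start_day`, `end_day`.
#' @examples
#' treatment_window("first_half")        # days [0, 42)
#' treatment_window("custom", 7, 14)     # second week
#' @export
treatment_window <- function(label = c("full", "first_half", "custom"),
                             start_day = NULL, end_day = NULL,
                             treatment_days = 84) {
  label <- match.arg(label)
  if (label == "full") {
    start_day <- 0L; end_day <- as.integer(treatment_days)
  } else if (label == "first_half") {
    start_day <- 0L; end_day <- as.integer(floor(treatment_days / 2))
  } else {
    if (is.null(start_day) || is.null(end_day)) {
      stop("custom window needs start_day and end_day", call. = FALSE)
    }
  }
  if (end_day <= start_day) stop("end_day must exceed start_day", call. = FALSE)
  structure(list(label = label, start_day = as.integer(start_day),
                 end_day = as.integer(end_day)),
            class = "treatment_window")
}

sessions_in_window <- function(sessions, window, treatment_start) {
  if (nrow(sessions) == 0L) return(sessions)
  day <- local_day_index(sessions$start, sessions$tz_offset, treatment_start)
  sessions[day >= window$start_day & day < window$end_day, , drop = FALSE]
}

#' Quantity of app use
#'
#' Total active minutes over all sessions starting inside the window.
#'
#' @param sessions tibble of (merged, outlier-filtered) sessions for one
#'   participant.
#' @param window a [treatment_window()].
#' @param treatment_start Date of treatment day 0.
#' @return total active minutes (0 for no sessions).
#' @export
quantity_of_use <- function(sessions, window, treatment_start) {
  sw <- sessions_in_window(sessions, window, treatment_start)
  sum(sw$active_minutes)
}

#' Frequency of app use
#'
#' The mean break, in minutes, between consecutive sessions in the window
#' (end of one session to start of the next), and its natural logarithm.
#' With fewer than two sessions the feature is undefined and both values are
#' `NA` — the participant is excluded from frequency analyses rather than
#' raising an error.
#'
#' @inheritParams quantity_of_use
#' @return list with `mean_gap_min`, `log_mean_gap`, `n_sessions`.
#' @export
frequency_of_use <- function(sessions, window, treatment_start) {
  sw <- sessions_in_window(sessions, window, treatment_start)
  sw <- sw[order(sw$start), , drop = FALSE]
  n <- nrow(sw)
  if (n < 2L) {
    return(list(mean_gap_min = NA_real_, log_mean_gap = NA_real_,
                n_sessions = n))
  }
  gaps <- (as.numeric(sw$start[-1L]) - as.numeric(sw$end[-n])) / 60
  mg <- mean(gaps)
  list(mean_gap_min = mg, log_mean_gap = log(mg), n_sessions = n)
}

#' Number of distinct days with app use
#'
#' Counts distinct participant-local calendar dates containing at least one
#' session start within the window.
#'
#' @inheritParams quantity_of_use
#' @return integer count of days used.
#' @export
days_used <- function(sessions, window, treatment_start) {
  sw <- sessions_in_window(sessions, window, treatment_start)
  if (nrow(sw) == 0L) return(0L)
  length(unique(local_day_index(sw$start, sw$tz_offset, treatment_start)))
}

DURATION_BINS <- c(0, 5, 10, 20, 40, Inf)
DURATION_BIN_LABELS <- c("(0,5]", "(5,10]", "(10,20]", "(20,40]", "(40,Inf)")

#' Session-duration histogram
#'
#' Bins session active durations into (0,5], (5,10], (10,20], (20,40] and
#' (40, Inf) minutes — left-open, right-closed, so a 5.0-min session counts
#' as "<= 5 min". Percentages are reported to one decimal.
#'
#' @param sessions tibble of sessions (typically outlier-filtered).
#' @return tibble with `bin`, `count`, `pct`.
#' @export
duration_histogram <- function(sessions) {
  b <- cut(sessions$active_minutes, breaks = DURATION_BINS, right = TRUE,
           labels = DURATION_BIN_LABELS)
  counts <- as.integer(table(b))
  n <- sum(counts)
  tibble::tibble(
    bin = DURATION_BIN_LABELS,
    count = counts,
    pct = if (n == 0L) rep(0, 5L) else round(100 * counts / n, 1)
  )
}

#' Daily usage series
#'
#' Per-day total active minutes over the window (zero-filled): the data
#' behind a daily engagement heat map / line plot.
#'
#' @inheritParams quantity_of_use
#' @return numeric vector of length `end_day - start_day`, named by day index.
#' @export
daily_usage_series <- function(sessions, window, treatment_start) {
  days <- window$start_day:(window$end_day - 1L)
  out <- stats::setNames(numeric(length(days)), days)
  sw <- sessions_in_window(sessions, window, treatment_start)
  if (nrow(sw) > 0L) {
    d <- local_day_index(sw$start, sw$tz_offset, treatment_start)
    agg <- rowsum(sw$active_minutes, d)
    out[rownames(agg)] <- as.vector(agg)
  }
  out
}

#' Engagement feature table
#'
#' Computes, per participant, the engagement features fed to the outcome
#' statistics: quantity (total active minutes), frequency (mean and log-mean
#' inter-session gap), days used, and the session-duration histogram counts.
#'
#' @param sessions tibble of sessions for one or more participants.
#' @inheritParams quantity_of_use
#' @return tibble, one row per participant, with columns
#'   `participant_id,window,quantity_min,mean_gap_min,log_mean_gap,days_used,
#'   bin_le5,bin_5_10,bin_10_20,bin_20_40,bin_gt40`.
#' @export
engagement_features <- function(sessions, window, treatment_start) {
  ids <- sort(unique(sessions$participant_id))
  if (length(ids) == 0L) {
    return(tibble::tibble(
      participant_id = character(), window = character(),
      quantity_min = numeric(), mean_gap_min = numeric(),
      log_mean_gap = numeric(), days_used = integer(),
      bin_le5 = integer(), bin_5_10 = integer(), bin_10_20 = integer(),
      bin_20_40 = integer(), bin_gt40 = integer()
    ))
  }
  rows <- lapply(ids, function(id) {
    s <- sessions[sessions$participant_id == id, , drop = FALSE]
    fr <- frequency_of_use(s, window, treatment_start)
    h <- duration_histogram(sessions_in_window(s, window, treatment_start))
    qty <- quantity_of_use(s, window, treatment_start)
    du <- days_used(s, window, treatment_start)
    tibble::tibble(
      participant_id = id,
      window = window$label,
      quantity_min = qty,
      mean_gap_min = fr$mean_gap_min,
      log_mean_gap = fr$log_mean_gap,
      days_used = du,
      bin_le5 = h$count[1L], bin_5_10 = h$count[2L], bin_10_20 = h$count[3L],
      bin_20_40 = h$count[4L], bin_gt40 = h$count[5L]
    )
  })
  dplyr::bind_rows(rows)
}

#' Write an engagement feature table
#'
#' @param features tibble from [engagement_features()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_engagement_features <- function(features, path) {
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}
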
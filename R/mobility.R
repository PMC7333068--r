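# GPS mobility: stay detection, anonymization, home inference, time at home.
#
# A stay is a maximal run of consecutive fixes all within a small radius
# (default 100 m, great-circle) of the run's first fix whose time span
# reaches the dwell threshold (default 30 min); shorter runs are transit.
# Stays are anonymized to opaque random location IDs before any downstream
# use — no coordinates survive into the feature tables. Home is the ID with
# the most observation time between 3 AM and 6 AM local. Percent time at
# home is computed over labeled stay time within a +/- 3-day window around
# each clinical assessment.

gps_cols <- c("participant_id", "timestamp", "lat", "lon", "tz_offset")

#' Read a GPS fix log
#'
#' Reads the dialect `participant_id,timestamp,lat,lon,tz_offset` (ISO-8601
#' UTC timestamps, WGS84 degrees). Fixes are returned time-ordered within
#' participant; out-of-range coordinates are an error.
#'
#' @param path path to a GPS CSV file.
#' @return tibble of fixes.
#' @export
read_gps_log <- function(path) {
  if (!file.exists(path)) stop("GPS log not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("participant_id", "timestamp", "lat", "lon")
  if (!all(need %in% names(raw))) {
    stop("GPS log must have header columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  if (!"tz_offset" %in% names(raw)) raw$tz_offset <- "+00:00"
  if (nrow(raw) == 0L) {
    return(tibble::tibble(participant_id = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          lat = numeric(), lon = numeric(),
                          tz_offset = character()))
  }
  ts <- parse_ts(raw$timestamp)
  bad <- which(is.na(ts))
  if (length(bad)) {
    stop("malformed timestamp in GPS log at line ", bad[1L] + 1L, call. = FALSE)
  }
  fx <- tibble::tibble(
    participant_id = raw$participant_id,
    timestamp = ts,
    lat = as.numeric(raw$lat),
    lon = as.numeric(raw$lon),
    tz_offset = raw$tz_offset
  )
  check_coords(fx$lat, fx$lon)
  parse_tz_offset(fx$tz_offset)
  fx[order(fx$participant_id, fx$timestamp), , drop = FALSE]
}

check_coords <- function(lat, lon) {
  if (any(is.na(lat) | is.na(lon) | abs(lat) > 90 | abs(lon) > 180)) {
    stop("GPS coordinates out of range (|lat| <= 90, |lon| <= 180)",
         call. = FALSE)
  }
  invisible(NULL)
}

#' Write a GPS fix log
#'
#' @param fixes tibble of GPS fixes.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gps_log <- function(fixes, path) {
  out <- tibble::tibble(
    participant_id = fixes$participant_id,
    timestamp = fmt_ts(fixes$timestamp),
    lat = fixes$lat, lon = fixes$lon,
    tz_offset = fixes$tz_offset
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

haversine_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2))
}

#' Detect stays (dwell clusters) in a GPS trace
#'
#' Sequential first-fix-anchored clustering: a run grows while each fix lies
#' within `radius_m` of the run's first fix; when it breaks, the run becomes
#' a stay if its time span reaches `dwell_min` minutes, otherwise it is
#' discarded as transit. A gap of more than `max_gap_min` minutes between
#' consecutive fixes also breaks the run, so unobserved stretches (e.g.
#' whole missing days) are never counted as dwell time. Deterministic and
#' invariant to duplicated consecutive fixes.
#'
#' @param fixes tibble of GPS fixes (time-ordered within participant).
#' @param radius_m cluster radius in meters (default 100).
#' @param dwell_min minimum dwell in minutes for a run to count as a stay
#'   (default 30).
#' @param max_gap_min maximum tolerated gap between consecutive fixes within
#'   a run, minutes (default 60, i.e. four missed 15-min samples).
#' @return tibble of stay clusters with centroids: `participant_id`, `start`,
#'   `end`, `dwell_min`, `n_fixes`, `lat`, `lon`, `tz_offset`.
#' @export
detect_stays <- function(fixes, radius_m = 100, dwell_min = 30,
                         max_gap_min = 60) {
  check_coords(fixes$lat, fixes$lon)
  idx <- split(seq_len(nrow(fixes)), fixes$participant_id)
  out <- lapply(idx, function(ix) {
    detect_stays_one(fixes[ix, , drop = FALSE], radius_m = radius_m,
                     dwell_min = dwell_min, max_gap_min = max_gap_min)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(participant_id = character(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          dwell_min = numeric(), n_fixes = integer(),
                          lat = numeric(), lon = numeric(),
                          tz_offset = character()))
  }
  res[order(res$participant_id, res$start), , drop = FALSE]
}

detect_stays_one <- function(fx, radius_m, dwell_min, max_gap_min) {
  n <- nrow(fx)
  if (n == 0L) return(NULL)
  tnum <- as.numeric(fx$timestamp)
  if (is.unsorted(tnum)) {
    o <- order(tnum)
    fx <- fx[o, , drop = FALSE]
    tnum <- tnum[o]
  }
  lat <- fx$lat; lon <- fx$lon
  # a run also breaks across an observation gap longer than max_gap_min,
  # so unobserved stretches never count as dwell time
  big_gap <- c(FALSE, diff(tnum) / 60 > max_gap_min)
  runs_start <- integer(0); runs_end <- integer(0)
  i <- 1L
  chunk <- 512L
  while (i <= n) {
    brk <- NA_integer_
    j <- i + 1L
    while (j <= n) {
      jj <- min(n, j + chunk - 1L)
      sl <- j:jj
      d <- haversine_m(lat[i], lon[i], lat[sl], lon[sl])
      hit <- which(d > radius_m | big_gap[sl])
      if (length(hit)) { brk <- j + hit[1L] - 1L; break }
      j <- jj + 1L
    }
    run_end <- if (is.na(brk)) n else brk - 1L
    runs_start <- c(runs_start, i)
    runs_end <- c(runs_end, run_end)
    i <- if (is.na(brk)) n + 1L else brk
  }
  span <- (tnum[runs_end] - tnum[runs_start]) / 60
  keep <- span >= dwell_min
  if (!any(keep)) return(NULL)
  rs <- runs_start[keep]; re <- runs_end[keep]
  csla <- cumsum(lat); cslo <- cumsum(lon)
  len <- re - rs + 1L
  tibble::tibble(
    participant_id = fx$participant_id[1L],
    start = fx$timestamp[rs],
    end = fx$timestamp[re],
    dwell_min = span[keep],
    n_fixes = len,
    lat = (csla[re] - csla[rs] + lat[rs]) / len,
    lon = (cslo[re] - cslo[rs] + lon[rs]) / len,
    tz_offset = fx$tz_offset[rs]
  )
}

#' Anonymize stay clusters to opaque location IDs
#'
#' Clusters whose centroids lie within `radius_m` of an already-seen place
#' are given the same random opaque ID (e.g. `"ID78421"`); distinct places
#' get distinct IDs. The output carries no coordinates and the place-to-ID
#' mapping is not exported, emulating on-device anonymization before data
#' leave the phone.
#'
#' @param stays stay clusters from [detect_stays()] (with centroids).
#' @param seed integer seed for the random ID assignment.
#' @param radius_m same-place radius in meters (default 100).
#' @return tibble of anonymized stay intervals: `participant_id`,
#'   `location_id`, `start`, `end`, `dwell_min`, `tz_offset`.
#' @export
anonymize_stays <- function(stays, seed, radius_m = 100) {
  empty <- tibble::tibble(participant_id = character(),
                          location_id = character(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          dwell_min = numeric(), tz_offset = character())
  if (nrow(stays) == 0L) return(empty)
  withr::with_seed(as.integer(seed), {
    parts <- lapply(split(stays, stays$participant_id), function(st) {
      st <- st[order(st$start), , drop = FALSE]
      rep_lat <- numeric(0); rep_lon <- numeric(0)
      place <- integer(nrow(st))
      for (k in seq_len(nrow(st))) {
        if (length(rep_lat)) {
          d <- haversine_m(st$lat[k], st$lon[k], rep_lat, rep_lon)
          hit <- which(d <= radius_m)
        } else hit <- integer(0)
        if (length(hit)) {
          place[k] <- hit[1L]
        } else {
          rep_lat <- c(rep_lat, st$lat[k]); rep_lon <- c(rep_lon, st$lon[k])
          place[k] <- length(rep_lat)
        }
      }
      ids <- paste0("ID", sample.int(999999L, length(rep_lat)))
      tibble::tibble(
        participant_id = st$participant_id,
        location_id = ids[place],
        start = st$start, end = st$end,
        dwell_min = st$dwell_min, tz_offset = st$tz_offset
      )
    })
    dplyr::bind_rows(parts)
  })
}

#' Write / read anonymized stay intervals
#'
#' The anonymized export dialect is
#' `participant_id,location_id,start,end,dwell_min` (plus `tz_offset`); no
#' coordinate columns exist in any downstream artifact.
#'
#' @param stays tibble of anonymized stays from [anonymize_stays()].
#' @param path CSV path.
#' @return `path` (write) or a tibble of stays (read).
#' @export
write_stays <- function(stays, path) {
  out <- tibble::tibble(
    participant_id = stays$participant_id,
    location_id = stays$location_id,
    start = fmt_ts(stays$start),
    end = fmt_ts(stays$end),
    dwell_min = stays$dwell_min,
    tz_offset = stays$tz_offset
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_stays
#' @export
read_stays <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"tz_offset" %in% names(raw)) raw$tz_offset <- "+00:00"
  tibble::tibble(
    participant_id = raw$participant_id,
    location_id = raw$location_id,
    start = parse_ts(raw$start),
    end = parse_ts(raw$end),
    dwell_min = as.numeric(raw$dwell_min),
    tz_offset = raw$tz_offset
  )
}

# Overlap, in minutes, of each stay with the recurring daily local-time
# window [win_start_h, win_end_h), summed over the days the stay spans.
night_overlap_minutes <- function(start, end, tz_offset,
                                  win_start_h = 3, win_end_h = 6) {
  off <- parse_tz_offset(tz_offset)
  s <- (as.numeric(start) + off) / 60  # local minutes since epoch
  e <- (as.numeric(end) + off) / 60
  vapply(seq_along(s), function(k) {
    d0 <- floor(s[k] / 1440); d1 <- floor(e[k] / 1440)
    days <- d0:d1
    sum(interval_overlap_min(s[k], e[k],
                             days * 1440 + win_start_h * 60,
                             days * 1440 + win_end_h * 60))
  }, numeric(1))
}

#' Infer the home location
#'
#' Home is the anonymized location ID with the greatest total observation
#' time between 3 AM and 6 AM participant-local, summed over the whole
#' trace. Residual exact ties are broken by the earliest-observed ID; with
#' no stay overlapping any night window, home is absent (`NA`).
#'
#' @param stays tibble of anonymized stays.
#' @param win_start_h,win_end_h local-clock bounds of the night window
#'   (default 3 and 6).
#' @return tibble with one row per participant: `participant_id`,
#'   `home_location_id` (or `NA`), `n_night_observations` (stays overlapping
#'   the night window), `night_minutes`.
#' @export
infer_home <- function(stays, win_start_h = 3, win_end_h = 6) {
  parts <- lapply(split(stays, stays$participant_id), function(st) {
    st <- st[order(st$start), , drop = FALSE]
    ov <- night_overlap_minutes(st$start, st$end, st$tz_offset,
                                win_start_h, win_end_h)
    tot <- rowsum(ov, st$location_id, reorder = FALSE)  # first-seen order
    best <- which.max(tot)  # ties -> earliest-observed id
    if (tot[best] <= 0) {
      return(tibble::tibble(participant_id = st$participant_id[1L],
                            home_location_id = NA_character_,
                            n_night_observations = 0L,
                            night_minutes = 0))
    }
    tibble::tibble(participant_id = st$participant_id[1L],
                   home_location_id = rownames(tot)[best],
                   n_night_observations = sum(ov > 0),
                   night_minutes = as.numeric(tot[best]))
  })
  dplyr::bind_rows(parts)
}

#' Assessment-centered analysis window
#'
#' The week around a clinical assessment: 3 days before, the day itself, and
#' 3 days after, truncated at treatment start (at baseline the app is
#' typically installed on assessment day, so no earlier data exist).
#'
#' @param assessment_day day index of the assessment.
#' @param window_days days on each side (default 3).
#' @param treatment_start_day truncation floor (default 0).
#' @return integer vector `c(start_day, end_day)`, both inclusive.
#' @examples
#' assessment_window(42)  # days 39..45
#' assessment_window(0)   # days 0..3
#' @export
assessment_window <- function(assessment_day, window_days = 3,
                              treatment_start_day = 0) {
  c(start_day = as.integer(max(treatment_start_day,
                               assessment_day - window_days)),
    end_day = as.integer(assessment_day + window_days))
}

#' Percent time at home in a window
#'
#' Of the labeled stay time falling inside the window, the percentage spent
#' at the inferred home location. Unlabeled time (transit, dwells under the
#' stay threshold) is excluded from the denominator. With no labeled stay
#' time in the window, or no inferred home, the feature is absent (`NA`).
#'
#' @param stays anonymized stays for one participant.
#' @param home one row of [infer_home()] output for that participant.
#' @param window inclusive day-index bounds from [assessment_window()].
#' @param treatment_start Date of treatment day 0.
#' @param fixes optional GPS fixes for the participant, used to count
#'   `missing_days` (days in the window with zero fixes).
#' @param phase optional phase label copied into the output.
#' @return one-row tibble: `participant_id`, `phase`, `pct_time_at_home`,
#'   `observed_minutes`, `missing_days`.
#' @export
percent_time_at_home <- function(stays, home, window, treatment_start,
                                 fixes = NULL, phase = NA_character_) {
  pid <- home$participant_id[1L]
  ws <- window[["start_day"]] * 1440
  we <- (window[["end_day"]] + 1L) * 1440
  st <- stays[stays$participant_id == pid, , drop = FALSE]

  missing_days <- NA_integer_
  if (!is.null(fixes)) {
    fx <- fixes[fixes$participant_id == pid, , drop = FALSE]
    days <- window[["start_day"]]:window[["end_day"]]
    obs <- unique(local_day_index(fx$timestamp, fx$tz_offset, treatment_start))
    missing_days <- sum(!(days %in% obs))
  }

  row <- function(pct, obs_min) {
    tibble::tibble(participant_id = pid, phase = phase,
                   pct_time_at_home = pct, observed_minutes = obs_min,
                   missing_days = missing_days)
  }
  if (nrow(st) == 0L || is.na(home$home_location_id[1L])) {
    return(row(NA_real_, 0))
  }
  off <- parse_tz_offset(st$tz_offset)
  s <- (as.numeric(st$start) + off) / 60 -
    as.numeric(treatment_origin(treatment_start)) / 60
  e <- (as.numeric(st$end) + off) / 60 -
    as.numeric(treatment_origin(treatment_start)) / 60
  ov <- interval_overlap_min(s, e, ws, we)
  total <- sum(ov)
  if (total <= 0) return(row(NA_real_, 0))
  at_home <- sum(ov[st$location_id == home$home_location_id[1L]])
  row(100 * at_home / total, total)
}

#' Mobility feature table around assessments
#'
#' Computes `pct_time_at_home` for every participant at every assessment
#' phase, using the +/- `window_days` assessment window.
#'
#' @param stays anonymized stays (all participants).
#' @param homes [infer_home()] output.
#' @param assessments tibble with `participant_id`, `phase`, `day`.
#' @param treatment_start Date of treatment day 0.
#' @param fixes optional GPS fixes for missing-day counts.
#' @param window_days days on each side of the assessment (default 3).
#' @return tibble, one row per participant x phase.
#' @export
mobility_features <- function(stays, homes, assessments, treatment_start,
                              fixes = NULL, window_days = 3) {
  rows <- lapply(seq_len(nrow(assessments)), function(k) {
    a <- assessments[k, , drop = FALSE]
    h <- homes[homes$participant_id == a$participant_id, , drop = FALSE]
    if (nrow(h) == 0L) {
      h <- tibble::tibble(participant_id = a$participant_id,
                          home_location_id = NA_character_,
                          n_night_observations = 0L, night_minutes = 0)
    }
    w <- assessment_window(a$day, window_days)
    percent_time_at_home(stays, h, w, treatment_start, fixes = fixes,
                         phase = a$phase)
  })
  dplyr::bind_rows(rows)
}

#' App use at home versus outside, by treatment phase
#'
#' For each phase, among session time that overlaps any labeled stay, the
#' percentage overlapping a stay at the inferred home. Sessions with no
#' concurrent stay (e.g. on GPS-missing days) are excluded from both
#' numerator and denominator.
#'
#' @param sessions merged sessions (all participants).
#' @param stays anonymized stays.
#' @param homes [infer_home()] output.
#' @param treatment_start Date of treatment day 0.
#' @param phase_bins named list of `c(start_day, end_day)` half-open day
#'   ranges; defaults to weeks 1-8, 9-10 and 11-12 of a 12-week course.
#' @return tibble with `phase`, `pct_at_home`, `labeled_minutes`,
#'   `n_sessions_labeled`.
#' @export
app_use_location_context <- function(sessions, stays, homes, treatment_start,
                                     phase_bins = list(weeks_1_8 = c(0, 56),
                                                       weeks_9_10 = c(56, 70),
                                                       weeks_11_12 = c(70, 84))) {
  home_ov <- numeric(nrow(sessions))
  any_ov <- numeric(nrow(sessions))
  for (pid in unique(sessions$participant_id)) {
    si <- which(sessions$participant_id == pid)
    st <- stays[stays$participant_id == pid, , drop = FALSE]
    if (nrow(st) == 0L) next
    hid <- homes$home_location_id[homes$participant_id == pid]
    hid <- if (length(hid)) hid[1L] else NA_character_
    ss <- as.numeric(sessions$start[si]) / 60
    se <- as.numeric(sessions$end[si]) / 60
    ts <- as.numeric(st$start) / 60
    te <- as.numeric(st$end) / 60
    ov <- outer(se, te, pmin) - outer(ss, ts, pmax)
    ov[ov < 0] <- 0
    any_ov[si] <- rowSums(ov)
    if (!is.na(hid)) {
      at_home <- st$location_id == hid
      home_ov[si] <- rowSums(ov[, at_home, drop = FALSE])
    }
  }
  day <- local_day_index(sessions$start, sessions$tz_offset, treatment_start)
  rows <- lapply(names(phase_bins), function(nm) {
    b <- phase_bins[[nm]]
    in_phase <- day >= b[1L] & day < b[2L] & any_ov > 0
    tibble::tibble(
      phase = nm,
      pct_at_home = if (any(in_phase)) {
        100 * sum(home_ov[in_phase]) / sum(any_ov[in_phase])
      } else NA_real_,
      labeled_minutes = sum(any_ov[in_phase]),
      n_sessions_labeled = sum(in_phase)
    )
  })
  dplyr::bind_rows(rows)
}

#' Day-level GPS missingness
#'
#' A study day is missing iff it contains zero GPS fixes for the
#' participant; the fraction is `missing_days / study_days`.
#'
#' @param fixes GPS fixes (all participants).
#' @param treatment_start Date of treatment day 0.
#' @param study_days number of study days (day indices `0:(study_days-1)`).
#' @return tibble per participant: `participant_id`, `missing_days`,
#'   `fraction`.
#' @export
gps_missingness <- function(fixes, treatment_start, study_days) {
  ids <- sort(unique(fixes$participant_id))
  rows <- lapply(ids, function(pid) {
    fx <- fixes[fixes$participant_id == pid, , drop = FALSE]
    obs <- unique(local_day_index(fx$timestamp, fx$tz_offset, treatment_start))
    obs <- obs[obs >= 0 & obs < study_days]
    miss <- study_days - length(obs)
    tibble::tibble(participant_id = pid, missing_days = as.integer(miss),
                   fraction = miss / study_days)
  })
  dplyr::bind_rows(rows)
}
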
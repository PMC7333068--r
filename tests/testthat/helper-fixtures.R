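# Fixture builders and independent oracles used across the suite.
# All oracles are deliberately naive (brute force / direct formula) and share
# no code with the implementation paths they check.

T0 <- as.POSIXct("2023-01-02 00:00:00", tz = "UTC")
D0 <- as.Date("2023-01-02")

ts_min <- function(min) T0 + min * 60

# Events from start minutes (since T0) and durations in minutes.
mk_events <- function(start_min, dur_min, pid = "p1") {
  tibble::tibble(
    participant_id = pid,
    start = ts_min(start_min),
    end = ts_min(start_min + dur_min),
    tz_offset = "+00:00"
  )
}

# Single-event sessions: wall span equals active duration.
mk_sessions <- function(start_min, active_min, pid = "p1") {
  tibble::tibble(
    participant_id = pid,
    start = ts_min(start_min),
    end = ts_min(start_min + active_min),
    active_minutes = active_min,
    n_events = 1L,
    tz_offset = "+00:00"
  )
}

mk_fixes <- function(min, lat, lon, pid = "p1") {
  tibble::tibble(
    participant_id = pid,
    timestamp = ts_min(min),
    lat = lat, lon = lon,
    tz_offset = "+00:00"
  )
}

# Non-overlapping random events for one participant: random gaps and
# durations on a minute grid.
random_events <- function(n, pid = "p1", max_gap = 180, max_dur = 30) {
  dur <- round(runif(n, 1, max_dur), 2)
  gap <- round(runif(n, 1, max_gap), 2)
  start <- cumsum(gap) + cumsum(c(0, dur[-n]))
  mk_events(start, dur, pid)
}

# O(n^2) brute-force burst-merge oracle: repeatedly merge any two groups of
# events whose gap-inflated intervals [min start, max end + gap) intersect.
oracle_merge <- function(events, gap_min) {
  n <- nrow(events)
  if (n == 0L) return(NULL)
  s <- as.numeric(events$start) / 60
  e <- as.numeric(events$end) / 60
  groups <- as.list(seq_len(n))
  repeat {
    merged <- FALSE
    for (a in seq_along(groups)) {
      if (merged) break
      for (b in seq_along(groups)) {
        if (a >= b) next
        ia <- groups[[a]]; ib <- groups[[b]]
        sa <- min(s[ia]); ea <- max(e[ia]) + gap_min
        sb <- min(s[ib]); eb <- max(e[ib]) + gap_min
        if (sa < eb && sb < ea) {
          groups[[a]] <- c(ia, ib)
          groups[[b]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  ord <- order(vapply(groups, function(g) min(s[g]), numeric(1)))
  groups <- groups[ord]
  data.frame(
    start_min = vapply(groups, function(g) min(s[g]), numeric(1)),
    end_min = vapply(groups, function(g) max(e[g]), numeric(1)),
    active_minutes = vapply(groups, function(g) sum(e[g] - s[g]), numeric(1)),
    n_events = lengths(groups)
  )
}

expect_merge_equals_oracle <- function(events, gap_min) {
  got <- merge_into_sessions(events, gap_min)
  want <- oracle_merge(events, gap_min)
  expect_equal(nrow(got), nrow(want))
  expect_equal(as.numeric(got$start) / 60, want$start_min)
  expect_equal(as.numeric(got$end) / 60, want$end_min)
  expect_equal(got$active_minutes, want$active_minutes, tolerance = 1e-9)
  expect_equal(got$n_events, want$n_events)
}

# Closed-form Pearson correlation (covariance over product of SDs).
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Minute-by-minute counting oracle for percent time at home.
oracle_pct_home <- function(stays, home_id, start_day, end_day) {
  mins <- (start_day * 1440):((end_day + 1L) * 1440 - 1L)
  s <- as.numeric(stays$start) / 60 - as.numeric(T0) / 60
  e <- as.numeric(stays$end) / 60 - as.numeric(T0) / 60
  in_any <- rep(FALSE, length(mins))
  in_home <- rep(FALSE, length(mins))
  for (k in seq_len(nrow(stays))) {
    hit <- mins >= s[k] & mins < e[k]
    in_any <- in_any | hit
    if (stays$location_id[k] == home_id) in_home <- in_home | hit
  }
  if (!any(in_any)) return(NA_real_)
  100 * sum(in_home) / sum(in_any)
}

# All-pairs single-linkage clustering oracle for stay detection on traces
# whose places are well separated relative to the radius.
oracle_stays <- function(fixes, radius_m = 100, dwell_min = 30) {
  d <- geosphere::distm(cbind(fixes$lon, fixes$lat))
  cl <- stats::cutree(stats::hclust(stats::as.dist(d), method = "single"),
                      h = radius_m)
  r <- rle(cl)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  span <- (as.numeric(fixes$timestamp[idx_end]) -
             as.numeric(fixes$timestamp[idx_start])) / 60
  keep <- span >= dwell_min
  data.frame(start = fixes$timestamp[idx_start[keep]],
             end = fixes$timestamp[idx_end[keep]],
             dwell_min = span[keep])
}

# Pipeline-level estimate of corr(log mean gap, percent improvement) on a
# generated cohort: sessionize, filter, full-window frequency, improvement
# from the assessment table.
estimate_freq_improve_r <- function(cohort) {
  cfg <- cohort$config
  sess <- filter_outlier_sessions(merge_into_sessions(cohort$events))$kept
  w <- treatment_window("full", treatment_days = cfg$treatment_days)
  ef <- engagement_features(sess, w, cfg$origin_date)
  a0 <- cohort$assessments[cohort$assessments$phase == "baseline", ]
  a2 <- cohort$assessments[cohort$assessments$phase == "posttreatment", ]
  imp <- percent_improvement(
    a0$ybocs_total,
    a2$ybocs_total[match(a0$participant_id, a2$participant_id)]
  )
  lg <- ef$log_mean_gap[match(a0$participant_id, ef$participant_id)]
  correlate(lg, imp)$r
}

# Pipeline-level estimate of corr(percent time at home, severity), pooled
# over the three assessment phases.
estimate_home_severity_r <- function(cohort, seed = cohort$config$seed) {
  cfg <- cohort$config
  st <- detect_stays(cohort$fixes)
  an <- anonymize_stays(st, seed = seed)
  hm <- infer_home(an)
  mob <- mobility_features(an, hm, cohort$assessments, cfg$origin_date)
  severity_home_correlation(cohort$assessments, mob)$r
}
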
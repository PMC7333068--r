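# Seeded synthetic cohorts with planted effect sizes.
#
# The generator emulates the data streams of a 12-week smartphone-CBT pilot:
# bursty, brief app usages whose daily rate declines across treatment;
# heavy-tailed (lognormal) session durations with most sessions <= 5 min;
# home-anchored mobility sampled every 15 min with heavy day-level GPS
# missingness; an at-home app-use preference that shifts outside the home in
# the final weeks; and integer severity scores at baseline / midpoint /
# posttreatment driven by a latent linear improvement trajectory. Two effects
# are planted with configurable sizes: the correlation between log mean
# inter-session gap and percent improvement, and the correlation between
# percent time at home and concurrent severity. Ground truth is kept apart
# from the observable files so recovery can be scored.

#' Synthetic cohort configuration
#'
#' Defaults encode the emulation targets: 3 declining to 0.5 sessions/day,
#' lognormal active durations with median ~3 min (~70% of raw durations
#' <= 5 min; the burst-merged majority stays <= 5 min), 60% of days missing
#' GPS at a 15-min sampling interval, an
#' at-home app-use schedule of 70% / 57% / 17% across weeks 1-8 / 9-10 /
#' 11-12, baseline severity ~ N(30, 4) truncated above 20, and planted
#' correlations of -0.6 (log gap vs improvement) and +0.5 (time at home vs
#' severity).
#'
#' @param n_participants cohort size.
#' @param treatment_days length of treatment (default 84 = 12 weeks).
#' @param seed root seed; all randomness derives from it via per-participant
#'   substreams `(seed + i * 9973) mod (2^31 - 1)`, so adding participants
#'   does not perturb earlier ones.
#' @param session_rate_start,session_rate_end sessions/day at day 0 and at
#'   the final day (linear decline).
#' @param duration_log_mean,duration_log_sd lognormal parameters of session
#'   active duration in minutes.
#' @param burst_prob probability a session is emitted as 2-3 raw events with
#'   short (< 60 min) internal breaks.
#' @param rho_freq_improve planted correlation between log mean gap and
#'   percent improvement.
#' @param rho_home_severity planted correlation between percent time at home
#'   and concurrent severity.
#' @param gps_day_missingness probability a day has no GPS fixes.
#' @param gps_interval_min GPS sampling interval in minutes.
#' @param n_away_locations number of distinct away places per participant.
#' @param home_use_schedule per-phase probabilities a session is placed at
#'   home (weeks 1-8, 9-10, 11-12).
#' @param baseline_ybocs_mean,baseline_ybocs_sd baseline severity
#'   distribution, truncated to scores > 20 (the eligibility floor).
#' @param improve_mean,improve_sd latent percent-improvement distribution.
#' @param gap_log_sd between-participant SD of log mean gap.
#' @param home_pct_mean,home_pct_sd center and spread of the time-at-home
#'   targets (percent), clamped to [40, 98].
#' @param origin_date local calendar date of treatment day 0.
#' @param tz_offset participant timezone offset string.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 10,
                          treatment_days = 84,
                          seed = 1,
                          session_rate_start = 3,
                          session_rate_end = 0.5,
                          duration_log_mean = log(3),
                          duration_log_sd = 0.9,
                          burst_prob = 0.3,
                          rho_freq_improve = -0.6,
                          rho_home_severity = 0.5,
                          gps_day_missingness = 0.60,
                          gps_interval_min = 15,
                          n_away_locations = 3,
                          home_use_schedule = c(0.70, 0.57, 0.17),
                          baseline_ybocs_mean = 30,
                          baseline_ybocs_sd = 4,
                          improve_mean = 45,
                          improve_sd = 15,
                          gap_log_sd = 0.7,
                          home_pct_mean = 70,
                          home_pct_sd = 12,
                          origin_date = as.Date("2023-01-02"),
                          tz_offset = "+00:00") {
  cfg <- list(n_participants = as.integer(n_participants),
              treatment_days = as.integer(treatment_days), seed = as.integer(seed),
              session_rate_start = session_rate_start,
              session_rate_end = session_rate_end,
              duration_log_mean = duration_log_mean,
              duration_log_sd = duration_log_sd,
              burst_prob = burst_prob,
              rho_freq_improve = rho_freq_improve,
              rho_home_severity = rho_home_severity,
              gps_day_missingness = gps_day_missingness,
              gps_interval_min = gps_interval_min,
              n_away_locations = as.integer(n_away_locations),
              home_use_schedule = home_use_schedule,
              baseline_ybocs_mean = baseline_ybocs_mean,
              baseline_ybocs_sd = baseline_ybocs_sd,
              improve_mean = improve_mean, improve_sd = improve_sd,
              gap_log_sd = gap_log_sd,
              home_pct_mean = home_pct_mean, home_pct_sd = home_pct_sd,
              origin_date = as.Date(origin_date), tz_offset = tz_offset)
  probs <- c(cfg$burst_prob, cfg$gps_day_missingness, cfg$home_use_schedule)
  if (any(probs < 0 | probs > 1)) {
    stop("infeasible config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(cfg$rho_freq_improve) >= 1 || abs(cfg$rho_home_severity) >= 1) {
    stop("infeasible config: planted |rho| must be < 1", call. = FALSE)
  }
  if (cfg$n_participants < 1L || cfg$treatment_days < 2L ||
      cfg$session_rate_start <= 0 || cfg$session_rate_end <= 0 ||
      cfg$gps_interval_min <= 0 || cfg$duration_log_sd <= 0) {
    stop("infeasible config: sizes, rates and scales must be positive",
         call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

participant_seed <- function(root_seed, i) {
  as.integer((as.numeric(root_seed) + i * 9973) %% 2147483647)
}

# Pooled (across the three assessment phases) mean and SD of the latent
# severity, used to standardize severity when planting the home-time
# coupling. Derived from the configured baseline and improvement moments for
# severity(t) = baseline * (1 - improvement/100 * t), t in {0, 1/2, 1}.
severity_pool_moments <- function(cfg) {
  f <- c(0, 0.5, 1)
  mb <- cfg$baseline_ybocs_mean; sb <- cfg$baseline_ybocs_sd
  mi <- cfg$improve_mean; si <- cfg$improve_sd
  m_t <- mb * (1 - mi * f / 100)
  e2 <- (mb^2 + sb^2) * ((1 - mi * f / 100)^2 + (si * f / 100)^2)
  m <- mean(m_t)
  v <- mean(e2) - m^2
  list(mean = m, sd = sqrt(v))
}

phase_of_day <- function(day, treatment_days) {
  cuts <- c(2 / 3, 5 / 6) * treatment_days
  1L + (day >= cuts[1L]) + (day >= cuts[2L])
}

#' Generate a synthetic cohort
#'
#' Draws, per participant, a latent (improvement, usage-frequency) pair from
#' a bivariate normal with the planted correlation; emits bursty sessions
#' from a daily Poisson process with linearly declining rate; builds the
#' severity trajectory and reads it off at days 0, `treatment_days/2` and
#' `treatment_days` with +/- 1 integer noise clamped to [0, 48]; simulates
#' home-anchored mobility whose daily away time tracks current severity to
#' realize the planted time-at-home coupling; samples GPS fixes every
#' `gps_interval_min` minutes on non-missing days; and places app sessions
#' at home or away per the phase schedule. Regeneration from the same config
#' is byte-identical.
#'
#' @param config a [cohort_config()].
#' @param streams which observable streams to materialize (any of
#'   `"usage"`, `"gps"`, `"assessments"`); latent structure is always drawn
#'   identically, so a subset is a strict projection of the full cohort.
#' @return a `synthetic_cohort` list: `config`, `truth` (per-participant
#'   latent parameters, never read by the pipeline), `events`, `fixes`,
#'   `assessments`.
#' @export
generate_cohort <- function(config,
                            streams = c("usage", "gps", "assessments")) {
  stopifnot(inherits(config, "cohort_config"))
  streams <- match.arg(streams, several.ok = TRUE)
  cfg <- config
  td <- cfg$treatment_days
  days <- 0:(td - 1L)
  assess_days <- c(0L, as.integer(floor(td / 2)), td)
  pool <- severity_pool_moments(cfg)
  origin <- treatment_origin(cfg$origin_date)
  tgrid <- seq(0, 1440 - cfg$gps_interval_min, by = cfg$gps_interval_min)

  truth_rows <- vector("list", cfg$n_participants)
  event_rows <- vector("list", cfg$n_participants)
  fix_rows <- vector("list", cfg$n_participants)
  assess_rows <- vector("list", cfg$n_participants)

  for (i in seq_len(cfg$n_participants)) {
    pid <- sprintf("P%03d", i)
    pseed <- participant_seed(cfg$seed, i)
    withr::with_seed(pseed, {
      ## latent engagement / outcome pair
      z1 <- rnorm(1)
      z2 <- cfg$rho_freq_improve * z1 +
        sqrt(1 - cfg$rho_freq_improve^2) * rnorm(1)
      improvement <- cfg$improve_mean + cfg$improve_sd * z1
      rate_mult <- exp(-cfg$gap_log_sd * z2)

      ## baseline severity, truncated above the eligibility floor
      repeat {
        b <- round(rnorm(1, cfg$baseline_ybocs_mean, cfg$baseline_ybocs_sd))
        if (b > 20 && b <= 48) break
      }
      sev_true <- b * (1 - improvement / 100 * assess_days / td)
      scores <- pmin(48L, pmax(0L, as.integer(round(sev_true)) +
                                 sample(-1:1, 3L, replace = TRUE)))

      ## mobility schedule: time-at-home targets coupled to severity
      zs <- (sev_true - pool$mean) / pool$sd
      e3 <- rnorm(3)
      pct_anchor <- pmin(98, pmax(40, cfg$home_pct_mean + cfg$home_pct_sd *
                                    (cfg$rho_home_severity * zs +
                                       sqrt(1 - cfg$rho_home_severity^2) * e3)))
      pct_day <- approx(assess_days, pct_anchor, xout = days, rule = 2)$y
      away_A <- pmin(900, (1 - pct_day / 100) * 1440)
      away_A[away_A < 30] <- 0
      away_start <- 420 + runif(td) * (900 - away_A)
      away_loc_idx <- sample.int(cfg$n_away_locations, td, replace = TRUE)
      gps_missing <- runif(td) < cfg$gps_day_missingness

      ## geography
      home_lat <- runif(1, 35, 45); home_lon <- runif(1, -100, -80)
      brg <- runif(cfg$n_away_locations, 0, 360)
      dst <- runif(cfg$n_away_locations, 800, 3000)
      awy <- geosphere::destPoint(c(home_lon, home_lat), brg, dst)
      away_lat <- awy[, 2L]; away_lon <- awy[, 1L]

      ## sessions: daily Poisson counts with linearly declining rate
      rate_d <- cfg$session_rate_start +
        (cfg$session_rate_end - cfg$session_rate_start) * days / (td - 1L)
      n_d <- rpois(td, rate_mult * rate_d)
      N <- sum(n_d)
      ev <- NULL
      if (N > 0L) {
        s_day <- rep(days, n_d)
        ph <- phase_of_day(s_day, td)
        at_home <- runif(N) < cfg$home_use_schedule[ph]
        A <- away_A[s_day + 1L]; as_ <- away_start[s_day + 1L]
        u_home <- runif(N) * (1440 - A)
        m_home <- ifelse(u_home >= as_, u_home + A, u_home)
        m_away <- as_ + runif(N) * A
        m <- ifelse(at_home | A == 0, m_home, m_away)
        dur <- rlnorm(N, cfg$duration_log_mean, cfg$duration_log_sd)
        start_abs <- s_day * 1440 + m

        ## burst splitting into raw events
        is_burst <- runif(N) < cfg$burst_prob
        k_ev <- ifelse(is_burst, sample(2:3, N, replace = TRUE), 1L)
        M <- sum(k_ev)
        sidx <- rep(seq_len(N), k_ev)
        j <- sequence(k_ev)
        w <- runif(M, 0.2, 1)
        wsum <- as.vector(rowsum(w, sidx))[sidx]
        ev_dur <- dur[sidx] * w / wsum
        brk <- ifelse(j == 1L, 0, runif(M, 2, 45))
        step <- ifelse(j == 1L, 0, c(0, ev_dur[-M]) + brk)
        cstep <- cumsum(step)
        first_idx <- rep(cumsum(c(0L, k_ev[-N])) + 1L, k_ev)
        offset <- cstep - cstep[first_idx]
        ev_start <- start_abs[sidx] + offset
        ev_end <- ev_start + ev_dur

        ## sort and enforce non-overlap (shift later events forward)
        o <- order(ev_start)
        ev_start <- ev_start[o]; ev_end <- ev_end[o]
        if (M > 1L) {
          for (t in 2:M) {
            if (ev_start[t] < ev_end[t - 1L] + 0.5) {
              delta <- ev_end[t - 1L] + 0.5 - ev_start[t]
              ev_start[t] <- ev_start[t] + delta
              ev_end[t] <- ev_end[t] + delta
            }
          }
        }
        s_sec <- round(ev_start * 60); e_sec <- pmax(round(ev_end * 60),
                                                     round(ev_start * 60) + 1)
        ev <- tibble::tibble(
          participant_id = pid,
          start = origin + s_sec, end = origin + e_sec,
          tz_offset = cfg$tz_offset
        )
      }

      ## GPS fixes on non-missing days
      fx <- NULL
      if ("gps" %in% streams) {
        obs_days <- days[!gps_missing]
        if (length(obs_days)) {
          day_rep <- rep(obs_days, each = length(tgrid))
          tod <- rep(tgrid, times = length(obs_days))
          A <- away_A[day_rep + 1L]; as_ <- away_start[day_rep + 1L]
          loci <- away_loc_idx[day_rep + 1L]
          in_away <- A > 0 & tod >= as_ & tod < as_ + A
          lat0 <- ifelse(in_away, away_lat[loci], home_lat)
          lon0 <- ifelse(in_away, away_lon[loci], home_lon)
          nfix <- length(lat0)
          lat <- lat0 + rnorm(nfix, 0, 10) / 111320
          lon <- lon0 + rnorm(nfix, 0, 10) /
            (111320 * cos(lat0 * pi / 180))
          fx <- tibble::tibble(
            participant_id = pid,
            timestamp = origin + (day_rep * 1440 + tod) * 60,
            lat = lat, lon = lon, tz_offset = cfg$tz_offset
          )
        }
      }

      truth_rows[[i]] <- tibble::tibble(
        participant_id = pid, seed = pseed,
        improvement_true = improvement,
        baseline_true = b,
        z_gap = z2, rate_mult = rate_mult,
        sev_true_baseline = sev_true[1L], sev_true_mid = sev_true[2L],
        sev_true_post = sev_true[3L],
        pct_home_target_baseline = pct_anchor[1L],
        pct_home_target_mid = pct_anchor[2L],
        pct_home_target_post = pct_anchor[3L],
        home_lat = home_lat, home_lon = home_lon
      )
      if ("usage" %in% streams && !is.null(ev)) event_rows[[i]] <- ev
      if (!is.null(fx)) fix_rows[[i]] <- fx
      if ("assessments" %in% streams) {
        assess_rows[[i]] <- tibble::tibble(
          participant_id = pid,
          phase = c("baseline", "midpoint", "posttreatment"),
          day = assess_days, ybocs_total = scores
        )
      }
    })
  }

  events <- dplyr::bind_rows(event_rows)
  if (nrow(events) == 0L) events <- empty_events()
  structure(list(
    config = cfg,
    truth = dplyr::bind_rows(truth_rows),
    events = events,
    fixes = dplyr::bind_rows(fix_rows),
    assessments = dplyr::bind_rows(assess_rows)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", x$config$n_participants, "participants,",
      x$config$treatment_days, "days, seed", x$config$seed, "\n")
  cat("  usage events:", nrow(x$events),
      "| GPS fixes:", nrow(x$fixes),
      "| assessments:", nrow(x$assessments), "\n")
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `usage.csv`, `gps.csv` and `assessments.csv` in the pipeline input
#' dialects, plus `ground_truth_synthetic.json` holding the latent
#' parameters and config. The ground-truth file is clearly named and is
#' never read by the pipeline.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  write_usage_log(cohort$events, file.path(dir, "usage.csv"))
  fx <- cohort$fixes
  if (is.null(fx) || nrow(fx) == 0L) {
    fx <- tibble::tibble(participant_id = character(),
                         timestamp = as.POSIXct(character(), tz = "UTC"),
                         lat = numeric(), lon = numeric(),
                         tz_offset = character())
  }
  write_gps_log(fx, file.path(dir, "gps.csv"))
  as_ <- cohort$assessments
  if (is.null(as_) || nrow(as_) == 0L) {
    as_ <- tibble::tibble(participant_id = character(), phase = character(),
                          day = integer(), ybocs_total = integer())
  }
  readr::write_csv(as_, file.path(dir, "assessments.csv"), progress = FALSE)
  gt <- list(config = unclass(cohort$config), truth = cohort$truth)
  gt$config$origin_date <- format(gt$config$origin_date)
  jsonlite::write_json(gt, file.path(dir, "ground_truth_synthetic.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read an assessment table
#'
#' Dialect: `participant_id,phase,day,ybocs_total`.
#'
#' @param path CSV path.
#' @return tibble of assessments.
#' @export
read_assessments <- function(path) {
  if (!file.exists(path)) stop("assessment file not found: ", path,
                               call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("participant_id", "phase", "day", "ybocs_total")
  if (!all(need %in% names(raw))) {
    stop("assessments must have header columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  out <- tibble::tibble(
    participant_id = raw$participant_id,
    phase = raw$phase,
    day = as.integer(raw$day),
    ybocs_total = as.integer(raw$ybocs_total)
  )
  if (any(out$ybocs_total < 0 | out$ybocs_total > 48, na.rm = TRUE)) {
    stop("ybocs_total must lie in [0, 48]", call. = FALSE)
  }
  out
}
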
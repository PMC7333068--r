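# End-to-end orchestration: ingest -> sessionize -> features -> statistics
# -> report bundle. All tunables default to the study's stated thresholds
# (60-min merge gap, 60-min outlier cutoff, 100 m stay radius, 30-min dwell,
# 3-6 AM night window, +/- 3-day assessment windows, 6000 resampling
# iterations).

REPORT_SCHEMA_VERSION <- "1.0"

#' Pipeline run configuration
#'
#' @param input_dir directory holding `usage.csv`, `gps.csv`,
#'   `assessments.csv`.
#' @param output_dir directory for the report bundle.
#' @param gap_threshold_min burst-merge gap threshold, minutes.
#' @param outlier_max_min session outlier cutoff, active minutes.
#' @param merge_before_outlier if `TRUE` (default) burst merging happens
#'   before outlier removal; `FALSE` applies the cutoff to raw events first.
#' @param stay_radius_m stay-detection radius, meters.
#' @param dwell_min stay dwell threshold, minutes.
#' @param night_window local-clock hours bounding the home-inference night
#'   window.
#' @param assessment_window_days days on each side of an assessment.
#' @param resample_iterations single-timepoint resampling iterations.
#' @param seed seed for anonymization and resampling.
#' @param improvement_scale `"percent"` (0-100) or `"proportion"` (0-1).
#' @param treatment_start Date of treatment day 0 shared by the cohort.
#' @param treatment_days study length in days.
#' @return a validated `run_config` list.
#' @export
run_config <- function(input_dir = ".", output_dir = ".",
                       gap_threshold_min = 60, outlier_max_min = 60,
                       merge_before_outlier = TRUE,
                       stay_radius_m = 100, dwell_min = 30,
                       night_window = c(3, 6),
                       assessment_window_days = 3,
                       resample_iterations = 6000,
                       seed = 1,
                       improvement_scale = c("percent", "proportion"),
                       treatment_start = as.Date("2023-01-02"),
                       treatment_days = 84) {
  improvement_scale <- match.arg(improvement_scale)
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              gap_threshold_min = gap_threshold_min,
              outlier_max_min = outlier_max_min,
              merge_before_outlier = isTRUE(merge_before_outlier),
              stay_radius_m = stay_radius_m, dwell_min = dwell_min,
              night_window = night_window,
              assessment_window_days = as.integer(assessment_window_days),
              resample_iterations = as.integer(resample_iterations),
              seed = as.integer(seed),
              improvement_scale = improvement_scale,
              treatment_start = as.Date(treatment_start),
              treatment_days = as.integer(treatment_days))
  pos <- c(cfg$gap_threshold_min, cfg$outlier_max_min, cfg$stay_radius_m,
           cfg$dwell_min, cfg$assessment_window_days, cfg$resample_iterations)
  if (any(pos <= 0)) stop("all thresholds must be positive", call. = FALSE)
  structure(cfg, class = "run_config")
}

try_stat <- function(expr) {
  tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Reads the three dialect files from `config$input_dir`, sessionizes usage,
#' derives engagement and mobility features, runs the outcome statistics,
#' and writes a report bundle to `config$output_dir`: a descriptive summary
#' CSV (`table1.csv`), the per-day usage matrix (`daily_usage.csv`), the
#' pooled severity-vs-home-time pairs (`severity_home_pairs.csv`), and a
#' versioned JSON report (`report.json`) with every statistic, the seeds,
#' and the exclusion log. Participants with fewer than 2 sessions are
#' excluded from frequency analyses with a logged reason, not an error; a
#' missing input file is an error.
#'
#' @param config a [run_config()].
#' @return the report, invisibly (a list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  paths <- file.path(config$input_dir, c("usage.csv", "gps.csv",
                                         "assessments.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  events <- read_usage_log(paths[1L])
  fixes <- read_gps_log(paths[2L])
  assessments <- read_assessments(paths[3L])
  ts <- config$treatment_start
  td <- config$treatment_days

  ## sessionization (merge-first by default; see merge_before_outlier)
  if (config$merge_before_outlier) {
    merged <- merge_into_sessions(events, config$gap_threshold_min)
    flt <- filter_outlier_sessions(merged, config$outlier_max_min)
  } else {
    raw_sessions <- merge_into_sessions(events, gap_threshold_min = 1e-9)
    kept_events <- filter_outlier_sessions(raw_sessions,
                                           config$outlier_max_min)$kept
    merged <- merge_into_sessions(kept_events, config$gap_threshold_min)
    flt <- list(kept = merged, removed = empty_sessions())
  }
  sessions <- flt$kept

  participants <- sort(unique(c(events$participant_id,
                                assessments$participant_id,
                                fixes$participant_id)))

  ## engagement features over both windows
  w_half <- treatment_window("first_half", treatment_days = td)
  w_full <- treatment_window("full", treatment_days = td)
  feat_half <- engagement_features(sessions, w_half, ts)
  feat_full <- engagement_features(sessions, w_full, ts)

  ## outcomes
  wide <- function(ph) {
    a <- assessments[assessments$phase == ph, c("participant_id", "ybocs_total")]
    stats::setNames(a$ybocs_total, a$participant_id)
  }
  yb0 <- wide("baseline"); yb1 <- wide("midpoint"); yb2 <- wide("posttreatment")
  ids_y <- names(yb0)[!is.na(yb0) & yb0 > 0]
  scale_div <- if (config$improvement_scale == "percent") 1 else 100
  imp_post <- stats::setNames(rep(NA_real_, length(participants)), participants)
  imp_mid <- imp_post
  ok <- intersect(ids_y, names(yb2)[!is.na(yb2)])
  imp_post[ok] <- percent_improvement(yb0[ok], yb2[ok]) / scale_div
  okm <- intersect(ids_y, names(yb1)[!is.na(yb1)])
  imp_mid[okm] <- percent_improvement(yb0[okm], yb1[okm]) / scale_div

  fv <- function(feat, col) {
    stats::setNames(rep(NA_real_, length(participants)), participants) |>
      (\(v) { v[feat$participant_id] <- feat[[col]]; v })()
  }
  q_full <- fv(feat_full, "quantity_min")
  g_full <- fv(feat_full, "log_mean_gap")

  exclusions <- list()
  few_sessions <- feat_full$participant_id[is.na(feat_full$log_mean_gap)]
  if (length(few_sessions)) {
    exclusions$frequency_lt2_sessions <- few_sessions
  }
  no_usage <- setdiff(participants, feat_full$participant_id)
  if (length(no_usage)) exclusions$no_usage_data <- no_usage

  cor_quantity <- try_stat(correlate(q_full, imp_post))
  cor_frequency <- try_stat(correlate(g_full, imp_post))
  regression <- try_stat({
    r <- regress_improvement(imp_post, q_full, g_full)
    r$coefficients <- as.data.frame(r$coefficients)
    r
  })

  ## mobility
  clusters <- detect_stays(fixes, config$stay_radius_m, config$dwell_min)
  stays <- anonymize_stays(clusters, seed = config$seed,
                           radius_m = config$stay_radius_m)
  homes <- infer_home(stays, config$night_window[1L], config$night_window[2L])
  no_home <- c(setdiff(participants, homes$participant_id),
               homes$participant_id[is.na(homes$home_location_id)])
  if (length(no_home)) exclusions$no_home_inferred <- sort(no_home)

  mob <- mobility_features(stays, homes, assessments, ts, fixes = fixes,
                           window_days = config$assessment_window_days)
  no_window <- unique(mob$participant_id[is.na(mob$pct_time_at_home)])
  if (length(no_window)) exclusions$missing_mobility_window <- no_window

  cor_home_severity <- try_stat(severity_home_correlation(assessments, mob))

  resample <- try_stat({
    ids3 <- intersect(names(yb0), unique(mob$participant_id))
    mk <- function(ph, src, col) {
      v <- stats::setNames(rep(NA_real_, length(ids3)), ids3)
      s <- src[src$phase == ph, , drop = FALSE]
      s <- s[s$participant_id %in% ids3, , drop = FALSE]
      v[s$participant_id] <- s[[col]]
      v
    }
    yb <- cbind(mk("baseline", assessments, "ybocs_total"),
                mk("midpoint", assessments, "ybocs_total"),
                mk("posttreatment", assessments, "ybocs_total"))
    hp <- cbind(mk("baseline", mob, "pct_time_at_home"),
                mk("midpoint", mob, "pct_time_at_home"),
                mk("posttreatment", mob, "pct_time_at_home"))
    rs <- resample_single_timepoint(yb, hp,
                                    n_iter = config$resample_iterations,
                                    seed = config$seed)
    rs$r_values <- NULL  # full draw vector stays out of the JSON report
    rs
  })

  miss <- gps_missingness(fixes, ts, td)
  mean_sev <- vapply(split(assessments$ybocs_total,
                           assessments$participant_id), mean, numeric(1))
  cor_missing <- try_stat({
    common <- intersect(miss$participant_id, names(mean_sev))
    m <- stats::setNames(miss$fraction, miss$participant_id)
    missingness_severity_check(m[common], mean_sev[common])
  })

  context <- try_stat(as.data.frame(
    app_use_location_context(sessions, stays, homes, ts,
                             phase_bins = default_phase_bins(td))))

  ## figure data products
  daily <- lapply(sort(unique(sessions$participant_id)), function(pid) {
    s <- sessions[sessions$participant_id == pid, , drop = FALSE]
    v <- daily_usage_series(s, w_full, ts)
    tibble::tibble(participant_id = pid, day = as.integer(names(v)),
                   active_minutes = as.numeric(v))
  })
  daily <- dplyr::bind_rows(daily)
  pairs <- dplyr::inner_join(assessments, mob,
                             by = c("participant_id", "phase"))
  pairs <- pairs[, c("participant_id", "phase", "day", "ybocs_total",
                     "pct_time_at_home")]

  msd <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_))
    c(mean(x), if (length(x) > 1L) sd(x) else NA_real_)
  }
  t1 <- rbind(
    c("percent_improvement", msd(imp_mid), msd(imp_post), NA, NA),
    c("quantity_of_use", msd(fv(feat_half, "quantity_min")), msd(q_full),
      if (is.null(cor_quantity$error)) c(cor_quantity$r, cor_quantity$p_value)
      else c(NA, NA)),
    c("frequency_of_use_log", msd(fv(feat_half, "log_mean_gap")), msd(g_full),
      if (is.null(cor_frequency$error)) c(cor_frequency$r, cor_frequency$p_value)
      else c(NA, NA))
  )
  table1 <- tibble::tibble(
    metric = t1[, 1L],
    mid_mean = as.numeric(t1[, 2L]), mid_sd = as.numeric(t1[, 3L]),
    post_mean = as.numeric(t1[, 4L]), post_sd = as.numeric(t1[, 5L]),
    r_with_improvement = as.numeric(t1[, 6L]), p_value = as.numeric(t1[, 7L])
  )

  n_excluded_freq <- length(exclusions$frequency_lt2_sessions %||% character()) +
    length(exclusions$no_usage_data %||% character())
  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    config = unclass(config) |> (\(x) {
      x$treatment_start <- format(x$treatment_start); x })(),
    counts = list(
      participants = length(participants),
      raw_events = nrow(events),
      sessions_kept = nrow(sessions),
      sessions_removed_outlier = nrow(flt$removed),
      gps_fixes = nrow(fixes),
      frequency_analyzed = length(participants) - n_excluded_freq,
      frequency_excluded = n_excluded_freq
    ),
    engagement = list(
      first_half = as.data.frame(feat_half),
      full = as.data.frame(feat_full)
    ),
    duration_histogram = as.data.frame(duration_histogram(sessions)),
    improvement = list(
      scale = config$improvement_scale,
      midpoint = as.list(imp_mid),
      posttreatment = as.list(imp_post)
    ),
    correlations = list(
      quantity_vs_improvement = cor_quantity,
      log_frequency_vs_improvement = cor_frequency,
      severity_vs_time_at_home = cor_home_severity,
      missingness_vs_severity = cor_missing
    ),
    regression = regression,
    resampling = resample,
    mobility = list(
      features = as.data.frame(mob),
      missingness = as.data.frame(miss),
      pooled_missing_fraction =
        if (nrow(miss)) sum(miss$missing_days) / (nrow(miss) * td) else NA,
      app_use_location_context = context
    ),
    exclusions = exclusions,
    seed = config$seed
  )

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(table1, file.path(config$output_dir, "table1.csv"),
                   progress = FALSE)
  readr::write_csv(daily, file.path(config$output_dir, "daily_usage.csv"),
                   progress = FALSE)
  readr::write_csv(pairs,
                   file.path(config$output_dir, "severity_home_pairs.csv"),
                   progress = FALSE)
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null", pretty = TRUE)
  invisible(report)
}

default_phase_bins <- function(treatment_days) {
  list(weeks_1_8 = c(0, 2 / 3 * treatment_days),
       weeks_9_10 = c(2 / 3 * treatment_days, 5 / 6 * treatment_days),
       weeks_11_12 = c(5 / 6 * treatment_days, treatment_days))
}

#' Read a flat key = value configuration file
#'
#' The CLI config format: one `key = value` pair per line, `#` comments.
#' Values are parsed as numbers where possible; comma-separated values
#' become numeric vectors.
#'
#' @param path config file path.
#' @return named list of values.
#' @export
read_flat_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!any(is.na(num))) num else val
  }
  out
}
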
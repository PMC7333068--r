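# Outcome statistics: percent improvement on the clinician-rated severity
# scale (0-48), normality screening with Shapiro-Wilk, Pearson correlations,
# a two-predictor OLS regression of improvement on quantity and (log)
# frequency of app use, and a single-timepoint resampling robustness check
# for the pooled severity / time-at-home correlation.

#' Percent improvement in symptom severity
#'
#' `100 * (baseline - post) / baseline`; negative values indicate worsening.
#'
#' @param baseline,post severity totals (baseline must be > 0). Vectorized.
#' @return percent improvement on the 0-100 scale.
#' @examples
#' percent_improvement(30, 15)  # 50
#' @export
percent_improvement <- function(baseline, post) {
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    stop("baseline score must be > 0", call. = FALSE)
  }
  100 * (baseline - post) / baseline
}

#' Normality screen with log-transform recommendation
#'
#' Shapiro-Wilk test plus a simple rule for heavy right tails: recommend a
#' log transform when normality is rejected (p < 0.05), all values are
#' positive, and the sample skewness is positive.
#'
#' @param values numeric vector, n >= 3, finite, non-constant.
#' @return list with `statistic`, `p_value`, `skewness`, `recommend_log`.
#' @export
normality_screen <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L || any(!is.finite(values))) {
    stop("normality_screen needs >= 3 finite values", call. = FALSE)
  }
  if (sd(values) == 0) {
    stop("normality test undefined for a constant vector", call. = FALSE)
  }
  sw <- shapiro.test(values)
  skew <- mean((values - mean(values))^3) / sd(values)^3
  list(statistic = unname(sw$statistic),
       p_value = sw$p.value,
       skewness = skew,
       recommend_log = sw$p.value < 0.05 && all(values > 0) && skew > 0)
}

#' Pearson correlation with listwise deletion
#'
#' Product-moment correlation with a two-sided p-value. Pairs with a missing
#' member are dropped listwise; fewer than 3 complete pairs or a constant
#' input is an error.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p_value`, `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  keep <- complete.cases(x, y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3L) stop("correlation needs >= 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant input", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Regress improvement on quantity and frequency of use
#'
#' Ordinary least squares with intercept:
#' `improvement ~ quantity + log_frequency`. Reports per-predictor
#' coefficient, t-based 95% CI and two-sided p. Near-collinear predictors
#' (condition number of the scaled design above `kappa_max`) are an error.
#'
#' @param y percent improvement (either 0-100 or 0-1 scale).
#' @param x1 quantity of app use (total active minutes).
#' @param x2 log mean inter-session gap (log frequency of use).
#' @param kappa_max collinearity guard on the design condition number
#'   (default 1e8).
#' @return list with `coefficients` (tibble: `term`, `beta`, `ci95_low`,
#'   `ci95_high`, `p_value`) and `n`.
#' @export
regress_improvement <- function(y, x1, x2, kappa_max = 1e8) {
  keep <- complete.cases(y, x1, x2)
  y <- as.numeric(y[keep]); x1 <- as.numeric(x1[keep]); x2 <- as.numeric(x2[keep])
  n <- length(y)
  if (n < 4L) stop("regression needs n > number of predictors + 1",
                   call. = FALSE)
  X <- cbind(1, x1, x2)
  if (kappa(X, exact = TRUE) > kappa_max) {
    stop("predictors x1 and x2 are (near-)collinear", call. = FALSE)
  }
  fit <- lm(y ~ x1 + x2)
  ci <- suppressWarnings(confint(fit, level = 0.95))
  sm <- suppressWarnings(summary(fit))$coefficients
  pv <- if (ncol(sm) >= 4L) sm[, 4L] else rep(NA_real_, 3L)
  terms <- c("(Intercept)", "x1", "x2")
  list(
    coefficients = tibble::tibble(
      term = c("intercept", "quantity", "log_frequency"),
      beta = unname(coef(fit)[terms]),
      ci95_low = unname(ci[terms, 1L]),
      ci95_high = unname(ci[terms, 2L]),
      p_value = unname(pv[terms])
    ),
    n = n
  )
}

#' Single-timepoint resampling robustness check
#'
#' When each participant contributes three paired observations (severity,
#' percent time at home at baseline, midpoint, posttreatment), the pooled
#' correlation could be inflated by the longitudinal structure. This check
#' re-runs the correlation `n_iter` times (default 6000), each time drawing
#' one of the three time points per participant uniformly at random.
#' Iterations with fewer than 3 usable pairs (after dropping missing pairs)
#' or a constant vector are recorded as `NA` and counted separately. Fully
#' reproducible from `seed`.
#'
#' @param ybocs n x 3 matrix of severity totals (columns = baseline,
#'   midpoint, posttreatment).
#' @param home_pct n x 3 matrix of percent time at home, same layout.
#' @param n_iter number of resampling iterations (default 6000).
#' @param seed integer seed, recorded in the result.
#' @return list with `r_values` (length `n_iter`, `NA` for degenerate
#'   iterations), `median_r`, `n_iterations`, `n_degenerate`, `seed`.
#' @export
resample_single_timepoint <- function(ybocs, home_pct, n_iter = 6000, seed) {
  ybocs <- as.matrix(ybocs); home_pct <- as.matrix(home_pct)
  if (!all(dim(ybocs) == dim(home_pct)) || ncol(ybocs) != 3L) {
    stop("ybocs and home_pct must be n x 3 matrices of equal shape",
         call. = FALSE)
  }
  np <- nrow(ybocs)
  r_values <- withr::with_seed(as.integer(seed), {
    idx <- matrix(sample.int(3L, np * n_iter, replace = TRUE), nrow = n_iter)
    vapply(seq_len(n_iter), function(it) {
      pick <- cbind(seq_len(np), idx[it, ])
      xs <- ybocs[pick]; ys <- home_pct[pick]
      keep <- complete.cases(xs, ys)
      xs <- xs[keep]; ys <- ys[keep]
      if (length(xs) < 3L || sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
      cor(xs, ys)
    }, numeric(1))
  })
  list(r_values = r_values,
       median_r = median(r_values, na.rm = TRUE),
       n_iterations = as.integer(n_iter),
       n_degenerate = sum(is.na(r_values)),
       seed = as.integer(seed))
}

#' Pooled severity / time-at-home correlation
#'
#' Pearson correlation between absolute severity totals and percent time at
#' home, pooled across assessment phases (three pairs per participant), the
#' primary digital-marker analysis.
#'
#' @param assessments tibble with `participant_id`, `phase`, `ybocs_total`.
#' @param mobility tibble with `participant_id`, `phase`,
#'   `pct_time_at_home` (rows with `NA` are dropped listwise).
#' @return list with `r`, `p_value`, `n` (as [correlate()]).
#' @export
severity_home_correlation <- function(assessments, mobility) {
  m <- dplyr::inner_join(assessments, mobility,
                         by = c("participant_id", "phase"))
  correlate(m$ybocs_total, m$pct_time_at_home)
}

#' Missingness-vs-severity sanity check
#'
#' Correlates per-participant GPS missing-day fractions with severity, to
#' check that missingness is plausibly random with respect to symptoms.
#'
#' @param missing_fraction per-participant missing-day fractions.
#' @param ybocs per-participant severity totals (same order).
#' @return list with `r`, `p_value`, `n`.
#' @export
missingness_severity_check <- function(missing_fraction, ybocs) {
  correlate(missing_fraction, ybocs)
}
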
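# Outcome statistics: improvement, normality screen, correlation,
# regression, resampling.

test_that("percent improvement follows the baseline-relative formula", {
  expect_equal(percent_improvement(30, 15), 50)
  expect_equal(percent_improvement(30, 30), 0)
  expect_error(percent_improvement(0, 10), "baseline")

  withr::local_seed(3)
  b <- sample(21:48, 30, replace = TRUE)
  p <- sample(0:48, 30, replace = TRUE)
  expect_equal(percent_improvement(b, p), 100 * (b - p) / b)
  # worsening flips the sign of the same magnitude
  expect_equal(percent_improvement(30, 40), -percent_improvement(30, 20))
})

test_that("normality screen recommends log only for skewed positive samples", {
  withr::local_seed(12)
  skewed <- exp(rnorm(50, 0, 1))
  ns <- normality_screen(skewed)
  expect_true(ns$recommend_log)
  expect_lt(ns$p_value, 0.05)

  normalish <- rnorm(50, 10, 1)
  expect_false(normality_screen(normalish)$recommend_log)

  expect_error(normality_screen(c(1, 2)), ">= 3")
  expect_error(normality_screen(rep(1, 10)), "constant")
})

test_that("correlate is exact on perfect linear relations and errors on bad input", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  expect_error(correlate(1:2, 1:2), ">= 3")
  expect_error(correlate(rep(1, 5), 1:5), "constant")
  expect_error(correlate(1:4, 1:5), "equal length")
})

test_that("correlate matches the closed-form oracle and drops pairs listwise", {
  withr::local_seed(21)
  for (rep in 1:10) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(correlate(x, y)$r, oracle_pearson(x, y), tolerance = 1e-12)
  }
  x <- c(rnorm(8), NA, rnorm(1)); y <- c(rnorm(9), NA)
  cc <- correlate(x, y)
  expect_equal(cc$n, 8L)
  keep <- !is.na(x) & !is.na(y)
  expect_equal(cc$r, oracle_pearson(x[keep], y[keep]), tolerance = 1e-12)
})

test_that("correlate is symmetric and affine-invariant up to slope sign", {
  withr::local_seed(22)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(correlate(x, y)$r, correlate(y, x)$r, tolerance = 1e-12)
  expect_equal(correlate(3 * x - 7, y)$r, correlate(x, y)$r, tolerance = 1e-12)
  expect_equal(correlate(-2 * x, y)$r, -correlate(x, y)$r, tolerance = 1e-12)
})

test_that("noiseless regression recovers the generating coefficients", {
  withr::local_seed(33)
  x1 <- rnorm(20); x2 <- rnorm(20)
  y <- 1 + 2 * x1 - 3 * x2
  fit <- regress_improvement(y, x1, x2)
  expect_equal(fit$coefficients$beta, c(1, 2, -3), tolerance = 1e-8)
  # CIs collapse onto the estimates with zero residual
  expect_equal(fit$coefficients$ci95_low, fit$coefficients$beta,
               tolerance = 1e-6)
  expect_equal(fit$coefficients$ci95_high, fit$coefficients$beta,
               tolerance = 1e-6)
})

test_that("with centered orthogonal predictors each beta is its bivariate slope", {
  x1 <- rep(c(-1, 1), each = 4)
  x2 <- rep(c(-1, 1), times = 4)  # orthogonal to x1, both centered
  withr::local_seed(34)
  y <- 5 + 0.8 * x1 - 1.3 * x2 + rnorm(8, 0, 0.1)
  fit <- regress_improvement(y, x1, x2)
  slope1 <- sum(x1 * (y - mean(y))) / sum(x1^2)
  slope2 <- sum(x2 * (y - mean(y))) / sum(x2^2)
  expect_equal(fit$coefficients$beta[2:3], c(slope1, slope2),
               tolerance = 1e-10)
})

test_that("regression matches the normal-equations oracle; collinearity errors", {
  withr::local_seed(35)
  for (rep in 1:5) {
    x1 <- rnorm(25); x2 <- rnorm(25); y <- rnorm(25)
    X <- cbind(1, x1, x2)
    beta_oracle <- solve(t(X) %*% X, t(X) %*% y)[, 1]
    fit <- regress_improvement(y, x1, x2)
    expect_equal(fit$coefficients$beta, unname(beta_oracle),
                 tolerance = 1e-10)
  }
  x <- rnorm(20)
  expect_error(regress_improvement(rnorm(20), x, 2 * x), "collinear")
})

test_that("resampling is seed-reproducible and degenerates to the full-data r", {
  withr::local_seed(44)
  np <- 10L
  yb1 <- sample(10:40, np)
  hp1 <- 50 + 0.8 * yb1 + rnorm(np, 0, 5)
  yb <- matrix(yb1, np, 3)   # identical triples per participant
  hp <- matrix(hp1, np, 3)
  rs <- resample_single_timepoint(yb, hp, n_iter = 500, seed = 9)
  full_r <- cor(yb1, hp1)
  expect_length(rs$r_values, 500L)
  expect_true(all(rs$r_values == full_r))
  expect_identical(rs$median_r, full_r)
  expect_equal(rs$n_degenerate, 0L)
  # bit-reproducible under the same seed
  rs2 <- resample_single_timepoint(yb, hp, n_iter = 500, seed = 9)
  expect_identical(rs$r_values, rs2$r_values)
})

test_that("a single resampling iteration matches a hand-traced draw", {
  withr::local_seed(45)
  np <- 8L
  yb <- matrix(sample(10:40, np * 3, replace = TRUE), np, 3)
  hp <- matrix(runif(np * 3, 0, 100), np, 3)
  rs <- resample_single_timepoint(yb, hp, n_iter = 1, seed = 123)
  idx <- withr::with_seed(123L, sample.int(3L, np, replace = TRUE))
  pick <- cbind(seq_len(np), idx)
  expect_equal(rs$r_values[1L], oracle_pearson(yb[pick], hp[pick]),
               tolerance = 1e-12)
})

test_that("iterations hitting missing pairs are dropped or flagged degenerate", {
  np <- 4L
  yb <- matrix(seq_len(np * 3), np, 3)
  hp <- yb + 1
  hp[, 2] <- NA  # midpoint column unusable
  rs <- resample_single_timepoint(yb, hp, n_iter = 200, seed = 7)
  expect_true(all(is.na(rs$r_values) | abs(rs$r_values - 1) < 1e-12))
  expect_gt(rs$n_degenerate, 0L)
  expect_equal(rs$median_r, 1, tolerance = 1e-12)
})

test_that("pooled severity-home correlation joins on participant and phase", {
  withr::local_seed(55)
  ids <- sprintf("p%02d", 1:10)
  phases <- c("baseline", "midpoint", "posttreatment")
  av <- expand.grid(participant_id = ids, phase = phases,
                    stringsAsFactors = FALSE)
  av$ybocs_total <- sample(5:40, nrow(av), replace = TRUE)
  mob <- av[, c("participant_id", "phase")]
  mob$pct_time_at_home <- 40 + 1.2 * av$ybocs_total + rnorm(nrow(av), 0, 8)
  got <- severity_home_correlation(tibble::as_tibble(av),
                                   tibble::as_tibble(mob))
  expect_equal(got$n, 30L)
  expect_equal(got$r, oracle_pearson(av$ybocs_total, mob$pct_time_at_home),
               tolerance = 1e-12)
})
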
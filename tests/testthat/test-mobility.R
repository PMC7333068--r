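# Stay detection, anonymization, home inference, time-at-home features.

PT_HOME <- c(lat = 40, lon = -90)

test_that("a dwell at one point becomes a single stay with the right span", {
  fx <- mk_fixes(c(0, 15, 30, 45), 40, -90)
  st <- detect_stays(fx)
  expect_equal(nrow(st), 1L)
  expect_equal(st$dwell_min, 45)
  expect_equal(st$n_fixes, 4L)
})

test_that("short dwells are discarded as transit", {
  far <- geosphere::destPoint(c(-90, 40), 90, 5000)
  fx <- mk_fixes(c(0, 10, 20), c(40, 40, far[2]), c(-90, -90, far[1]))
  expect_equal(nrow(detect_stays(fx)), 0L)
})

test_that("out-of-range coordinates are rejected", {
  expect_error(detect_stays(mk_fixes(c(0, 30), c(91, 40), c(0, 0))),
               "out of range")
})

test_that("two planted stays with transit match the all-pairs oracle", {
  b <- geosphere::destPoint(c(-90, 40), 90, 1000)  # 1 km east
  tr1 <- geosphere::destPoint(c(-90, 40), 90, 400)
  tr2 <- geosphere::destPoint(c(-90, 40), 90, 650)
  fx <- dplyr::bind_rows(
    mk_fixes(seq(0, 120, by = 10), 40, -90),
    mk_fixes(c(125, 130), c(tr1[2], tr2[2]), c(tr1[1], tr2[1])),
    mk_fixes(seq(140, 260, by = 10), b[2], b[1])
  )
  st <- detect_stays(fx)
  expect_equal(nrow(st), 2L)
  expect_equal(st$dwell_min, c(120, 120))
  want <- oracle_stays(fx)
  expect_equal(st$start, want$start)
  expect_equal(st$end, want$end)
  expect_equal(st$dwell_min, want$dwell_min)
})

test_that("stay detection ignores duplicated consecutive fixes", {
  fx <- mk_fixes(c(0, 15, 30, 45), 40, -90)
  dup <- fx[rep(seq_len(4), each = 2), , drop = FALSE]
  expect_equal(as.data.frame(detect_stays(dup)[, c("start", "end", "dwell_min")]),
               as.data.frame(detect_stays(fx)[, c("start", "end", "dwell_min")]))
})

test_that("a long gap between fixes breaks a run even at one place", {
  # same place before and after a fully unobserved day
  fx <- mk_fixes(c(0, 30, 60, 1500, 1530, 1560), 40, -90)
  st <- detect_stays(fx, max_gap_min = 60)
  expect_equal(nrow(st), 2L)
  expect_equal(st$dwell_min, c(60, 60))
})

test_that("anonymization maps same places to same ids and drops coordinates", {
  b <- geosphere::destPoint(c(-90, 40), 90, 5000)
  st <- detect_stays(dplyr::bind_rows(
    mk_fixes(seq(0, 60, 15), 40, -90),
    mk_fixes(seq(200, 260, 15), b[2], b[1]),
    mk_fixes(seq(400, 460, 15), 40, -90)
  ))
  an <- anonymize_stays(st, seed = 99)
  expect_equal(nrow(an), 3L)
  expect_equal(an$location_id[1L], an$location_id[3L])
  expect_false(an$location_id[1L] == an$location_id[2L])
  # schema-level privacy: nothing that can reconstruct coordinates
  expect_false(any(c("lat", "lon") %in% names(an)))
  expect_named(an, c("participant_id", "location_id", "start", "end",
                     "dwell_min", "tz_offset"))
})

test_that("permuting stay order relabels ids by a bijection", {
  withr::local_seed(31)
  pts <- geosphere::destPoint(c(-90, 40), runif(4, 0, 360), runif(4, 2000, 9000))
  segs <- lapply(1:8, function(k) {
    p <- (k - 1L) %% 4L + 1L
    mk_fixes(seq((k - 1) * 300, (k - 1) * 300 + 45, 15), pts[p, 2], pts[p, 1])
  })
  st <- detect_stays(dplyr::bind_rows(segs))
  a1 <- anonymize_stays(st, seed = 1)
  perm <- sample(nrow(st))
  a2 <- anonymize_stays(st[perm, ], seed = 2)
  a2 <- a2[order(a2$start), ]
  # same-place relation must be identical under both labelings
  expect_equal(outer(a1$location_id, a1$location_id, "=="),
               outer(a2$location_id, a2$location_id, "=="))
})

test_that("home is the modal 3-6 AM location; absent without night data", {
  # all stays at one place, spanning nights
  st1 <- anonymize_stays(detect_stays(mk_fixes(seq(0, 2 * 1440, 15), 40, -90)),
                         seed = 3)
  h1 <- infer_home(st1)
  expect_equal(h1$home_location_id, unique(st1$location_id))
  expect_gt(h1$night_minutes, 0)

  # daytime-only stays -> no home
  st2 <- anonymize_stays(detect_stays(mk_fixes(seq(600, 700, 15), 40, -90)),
                         seed = 3)
  h2 <- infer_home(st2)
  expect_true(is.na(h2$home_location_id))
  expect_equal(h2$n_night_observations, 0L)
})

test_that("home wins by night-overlap minutes over a daytime-dominant place", {
  b <- geosphere::destPoint(c(-90, 40), 90, 5000)
  # nights (2-7 AM) at home, long days (9 AM - 9 PM) at work, two days
  fx <- dplyr::bind_rows(
    mk_fixes(seq(2 * 60, 7 * 60, 15), 40, -90),
    mk_fixes(seq(9 * 60, 21 * 60, 15), b[2], b[1]),
    mk_fixes(seq(26 * 60, 31 * 60, 15), 40, -90),
    mk_fixes(seq(33 * 60, 45 * 60, 15), b[2], b[1])
  )
  an <- anonymize_stays(detect_stays(fx), seed = 8)
  hm <- infer_home(an)
  home_id_truth <- an$location_id[1L]  # first stay is the night stay
  expect_equal(hm$home_location_id, home_id_truth)
})

test_that("assessment windows are +/- 3 days truncated at treatment start", {
  expect_equal(unname(assessment_window(42)), c(39L, 45L))
  expect_equal(unname(assessment_window(0)), c(0L, 3L))
  expect_equal(unname(assessment_window(84)), c(81L, 87L))
})

test_that("percent time at home hits the 0 and 100 extremes", {
  b <- geosphere::destPoint(c(-90, 40), 90, 5000)
  night_home <- mk_fixes(c(seq(0, 7 * 60, 15), seq(22 * 60, 24 * 60, 15)),
                         40, -90)
  an <- anonymize_stays(detect_stays(night_home), seed = 4)
  hm <- infer_home(an)
  expect_equal(percent_time_at_home(an, hm, c(start_day = 0, end_day = 3),
                                    D0)$pct_time_at_home, 100)

  # all window time away from home
  fx2 <- dplyr::bind_rows(night_home,
                          mk_fixes(seq(5 * 1440, 5 * 1440 + 600, 15),
                                   b[2], b[1]))
  an2 <- anonymize_stays(detect_stays(fx2), seed = 4)
  hm2 <- infer_home(an2)
  p <- percent_time_at_home(an2, hm2, c(start_day = 5, end_day = 6), D0)
  expect_equal(p$pct_time_at_home, 0)
  # no labeled time in window -> absent
  p_none <- percent_time_at_home(an2, hm2, c(start_day = 20, end_day = 22), D0)
  expect_true(is.na(p_none$pct_time_at_home))
  expect_equal(p_none$observed_minutes, 0)
})

test_that("percent time at home matches the minute-counting oracle", {
  withr::local_seed(19)
  for (rep in 1:5) {
    pts <- geosphere::destPoint(c(-90, 40), runif(3, 0, 360),
                                runif(3, 2000, 8000))
    segs <- lapply(1:10, function(k) {
      p <- sample(3, 1)
      s0 <- (k - 1) * 500 + sample(0:59, 1)  # minute-aligned for the oracle
      mk_fixes(seq(s0, s0 + sample(c(45, 120, 300), 1), 15),
               pts[p, 2], pts[p, 1])
    })
    an <- anonymize_stays(detect_stays(dplyr::bind_rows(segs)), seed = rep)
    hm <- tibble::tibble(participant_id = "p1",
                         home_location_id = an$location_id[1L],
                         n_night_observations = 1L, night_minutes = 1)
    got <- percent_time_at_home(an, hm, c(start_day = 0, end_day = 3), D0)
    want <- oracle_pct_home(an, an$location_id[1L], 0, 3)
    expect_equal(got$pct_time_at_home, want, tolerance = 1e-9)
    expect_true(is.na(got$pct_time_at_home) ||
                  (got$pct_time_at_home >= 0 && got$pct_time_at_home <= 100))
  }
})

test_that("app-use location context splits session time at the home boundary", {
  stays <- tibble::tibble(
    participant_id = "p1",
    location_id = c("H", "A"),
    start = ts_min(c(0, 600)), end = ts_min(c(300, 900)),
    dwell_min = c(300, 300), tz_offset = "+00:00"
  )
  homes <- tibble::tibble(participant_id = "p1", home_location_id = "H",
                          n_night_observations = 1L, night_minutes = 1)
  # fully inside the home stay
  ctx <- app_use_location_context(mk_sessions(100, 30), stays, homes, D0,
                                  phase_bins = list(all = c(0, 84)))
  expect_equal(ctx$pct_at_home, 100)
  # half home, half away: 10 min at home end, 10 min at away start
  s2 <- tibble::tibble(participant_id = "p1", start = ts_min(290),
                       end = ts_min(610), active_minutes = 20, n_events = 1L,
                       tz_offset = "+00:00")
  ctx2 <- app_use_location_context(s2, stays, homes, D0,
                                   phase_bins = list(all = c(0, 84)))
  expect_equal(ctx2$pct_at_home, 50)
})

test_that("day-level GPS missingness counts zero-fix days", {
  full <- mk_fixes(seq(0, 10 * 1440 - 1, 120), 40, -90)
  m <- gps_missingness(full, D0, 10)
  expect_equal(m$missing_days, 0L)
  one <- mk_fixes(10, 40, -90)
  expect_equal(gps_missingness(one, D0, 10)$fraction, 0.9)

  # planted missingness pattern recovered exactly
  withr::local_seed(29)
  present <- sort(sample(0:83, 34))
  fx <- mk_fixes(present * 1440 + 300, 40, -90)
  got <- gps_missingness(fx, D0, 84)
  expect_equal(got$missing_days, 84L - 34L)
  expect_equal(got$fraction, 50 / 84)
})
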
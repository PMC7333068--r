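---
title: "Methods: passive smartphone engagement and mobility analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: passive smartphone engagement and mobility analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passivecbt)
```

## What this package models

Smartphone-delivered cognitive behavioral therapy (CBT) apps can passively
record two streams that clinician ratings cannot: *when and for how long*
the patient touches the therapy app, and *where* the patient is (via GPS).
`passivecbt` implements the analysis pipeline for a 12-week course of
app-delivered CBT for body dysmorphic disorder (BDD), in which severity is
rated on the clinician-administered BDD-YBOCS (12 items, total 0--48) at
baseline (week 0), midpoint (week 6) and posttreatment (week 12):

1. **Sessionization.** Raw usage events are brief on-app intervals. People
   use therapy apps in *bursts* — several short usages separated by short
   breaks — so events separated by less than a gap threshold are merged
   into one *session*. A session's duration is **active time**, the sum of
   its constituent event durations with breaks excluded: two 10-min usages
   with a 5-min break form one 20-min session. Sessions whose active time
   exceeds an a-priori outlier cutoff are removed.
2. **Engagement features.** *Quantity* of use is total active minutes in a
   treatment window; *frequency* of use is the mean break between
   consecutive sessions (end-to-start), analyzed as its natural logarithm
   because raw gaps are heavy-tailed; plus days used, a session-duration
   histogram, and a per-day usage series.
3. **Mobility features.** GPS fixes become *stays* (dwells of at least 30
   minutes within a 100 m radius), which are anonymized to opaque random
   location IDs before any downstream use. Home is the ID with the most
   observation time between 3 and 6 AM local. *Percent time at home* — a
   candidate digital marker of avoidance — is the share of labeled stay
   time at the home ID within the week surrounding each assessment
   (3 days before, the day, 3 days after, truncated at install day).
4. **Outcome statistics.** Percent improvement is
   $100 \times (\mathrm{baseline} - \mathrm{post}) / \mathrm{baseline}$.
   Engagement features are screened for normality (Shapiro-Wilk) and
   correlated with improvement (Pearson); a two-predictor OLS regression
   contrasts quantity against log-frequency. Severity and percent time at
   home are correlated pooling three pairs per participant, and a
   single-timepoint resampling check (6000 iterations drawing one of the
   three time points per participant) guards against inflation from the
   longitudinal pooling.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `gap_threshold_min` | 60 | min | breaks shorter than this merge bursty usages into one session |
| `outlier_max_min` | 60 | min | a-priori cutoff on a session's active time |
| `stay_radius_m` | 100 | m | spatial radius of a stay (location resolution of the capture) |
| `dwell_min` | 30 | min | minimum dwell for a place to be labeled at all |
| `max_gap_min` (stay detection) | 60 | min | observation gaps longer than this break a run, so unobserved stretches never count as dwell |
| night window | 3--6 | h, local | home inference window (virtually everyone is home then) |
| `assessment_window_days` | 3 | days | half-width of the mobility window around an assessment |
| `resample_iterations` | 6000 | -- | single-timepoint robustness draws |

## Design decisions that were genuinely open

* **Merge before outlier removal.** The order is not forced by the
  procedure description alone; merging first makes the 20-min worked
  example and the 60-min cutoff mutually consistent (a merged 61-min
  session is an outlier; its 10-min pieces are not). The other order is
  available via `merge_before_outlier = FALSE`.
* **Active time, not wall-clock span.** Forced by the worked example: two
  10-min usages with a 5-min break count 20 min, not 25.
* **Cutoff boundary.** "Approximately 60 min" is implemented as
  strictly-greater-than-60 removed, exactly 60 kept; the boundary is a
  parameter.
* **Gaps** are measured end-of-previous to start-of-next, and merging uses
  a strict `<` comparison, so a break of exactly the threshold starts a
  new session.
* **Natural log for frequency.** The printed transformed means pin the
  base: $\ln 512 = 6.24$ and $\ln 626 = 6.44$ to two decimals. The log is
  applied to the per-participant *mean* gap (log of mean, not mean of
  logs), which is what pairs 512 min with 6.24.
* **Stay detection algorithm.** Only the thresholds (100 m, 30 min) are
  prescribed, not the clusterer. We use a deterministic first-fix-anchored
  sequential scan — the simplest algorithm consistent with both
  thresholds — and test it against an independent all-pairs
  single-linkage oracle. Runs additionally break across observation gaps
  longer than `max_gap_min`; without this rule a participant observed at
  home on Monday and Wednesday with Tuesday unobserved would be credited
  a 48-hour home stay, biasing time-at-home upward.
* **Time-at-home denominator.** Labeled stay time only; transit and
  sub-threshold dwells are excluded, since only places held at least 30
  minutes receive an ID and the dichotomy is home / outside-of-home.
* **Ties and degenerate inputs.** Home ties are broken by
  earliest-observed ID (overlap minutes, not stay counts, already make
  exact ties rare). Fewer than two sessions makes frequency *absent*, not
  an error; a window with no labeled stay time makes percent time at home
  absent. Constant vectors are errors for correlation and normality
  testing. Near-collinear regression designs (condition number above
  `1e8`) are rejected by name.
* **Missingness.** A study day is missing iff it has zero fixes
  (day-level, not fix-level, missingness).

## The synthetic cohort generator

No raw participant data are distributed, so `generate_cohort()` emulates
the study conditions end to end; the generator is first-class, tested
code, and its defaults *are* the study conditions:

* sessions arrive from a daily Poisson process whose rate declines
  linearly from 3 to 0.5 sessions/day over 84 days (high early, low late);
* active durations are lognormal with median about 3 min (`meanlog =
  log(3)`, `sdlog = 0.9`), so roughly 70% of raw durations are at most 5
  minutes; with probability 0.3 a session is emitted as 2--3 raw events
  with breaks of under an hour;
* severity runs linearly from a baseline score (normal, mean 30, SD 4,
  truncated above the eligibility floor of 20) toward
  $\mathrm{baseline}\times(1-\mathrm{improvement}/100)$, read off at days
  0/42/84 with $\pm 1$ integer noise clamped to $[0, 48]$; the latent
  improvement is normal (mean 45, SD 15, matching the posttreatment
  improvement distribution's scale);
* mobility is home-anchored: nights at home, daytime away excursions
  whose daily total tracks *current* severity so that the planted
  time-at-home/severity coupling (+0.5 by default) emerges jointly with
  the severity decline; fixes arrive every 15 min, and whole days are
  deleted with probability 0.60;
* app sessions are placed at home with probability 0.70 / 0.57 / 0.17 in
  weeks 1--8 / 9--10 / 11--12, reproducing the home-to-outside shift;
* the planted engagement effect couples the per-participant log mean gap
  (between-participant SD 0.7, matching the printed log-gap SDs) to
  improvement with correlation $-0.6$ by default, via a latent bivariate
  normal.

All randomness flows from one root seed through per-participant
substreams, `(seed + i * 9973) mod (2^31 - 1)`, so regeneration is
byte-identical and earlier participants are unchanged when the cohort
grows. Ground truth (latent improvements, gap latents, home coordinates,
time-at-home targets) is stored apart from the observable files and never
read by the pipeline.

**What the generator does not emulate:** real street-network mobility,
semantic places (work, school), device-specific missingness mechanisms,
treatment content, or within-day autocorrelation of symptom severity.
Passing recovery tests therefore shows the *pipeline* is consistent and
unbiased under the stated generative assumptions — it does not validate
the clinical findings on real data, which this package cannot access.

## Numerical and testing choices

Histogram bins are left-open/right-closed, so a 5.0-min session counts as
"at most 5 min". Timestamps are stored UTC at second resolution with a
per-row timezone offset; calendar notions (days used, day indices, the
night window) use the participant-local clock. Distances are haversine
great-circle on WGS84.

The test suite exercises parameter recovery on 50 replicate cohorts of
n = 100 (planted correlations recovered within $\pm 0.1$ on average, and a
null cohort calibrated to mean $|r| < 0.15$), home-inference recovery on
50 seeded 14-day traces, exhaustive equivalence of the sessionizer with a
brute-force interval-merge oracle on all inputs of up to 6 events with
gaps from $\{1, 59, 60, 61, 120\}$ min, and closed-form oracles for the
correlation (to $10^{-12}$) and OLS (to $10^{-10}$). These problem sizes
were chosen to make sampling error in the recovery checks small relative
to the planted effects while keeping the default test run quick.

## Known limitations

* The stay detector is sequential and anchor-based; places closer
  together than the radius can alias onto one ID, and slow drifts within
  the radius extend a stay.
* Percent time at home conditions on labeled time only; a participant
  observed mostly in transit contributes little denominator and the
  feature is noisier for them.
* The resampling check treats the three time points as exchangeable
  within participant; it does not model serial dependence.
* With ten-participant cohorts (the pilot's scale) correlation estimates
  are extremely noisy; the pipeline reports effect sizes and leaves
  significance interpretation to the analyst.
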
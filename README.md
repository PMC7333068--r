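# passivecbt

Analysis pipeline for **passively collected smartphone data from
app-delivered cognitive behavioral therapy (CBT)** trials, built around a
12-week course of smartphone CBT for body dysmorphic disorder (BDD) with
clinician-rated severity (BDD-YBOCS, total 0–48) at weeks 0, 6 and 12.

It is written for digital-phenotyping and mobile-mental-health researchers
who have (or want to simulate) three per-participant streams — app-usage
event logs, GPS fix logs, and clinical assessments — and want reproducible
engagement and mobility features plus the outcome statistics that link them
to treatment response.

## What it computes

**Sessionization.** Raw on-app intervals separated by breaks `< 60` min are
merged into *sessions*; a session's duration is **active** time (sum of
event durations, breaks excluded), so two 10-min usages with a 5-min break
are one 20-min session. Sessions with active time `> 60` min are removed as
a-priori outliers.

**Engagement.** Quantity of use (total active minutes), frequency of use
(mean inter-session gap `ḡ`, analyzed as `ln ḡ` because gaps are
heavy-tailed), days used, session-duration histogram, and a per-day usage
series, over the first 6 weeks and the full 12 weeks.

**Mobility.** GPS fixes become *stays* (≥ 30 min within 100 m), anonymized
to opaque random location IDs with no surviving coordinates. Home is the ID
with the most 3–6 AM observation time. Percent time at home — a candidate
digital marker of avoidance — is computed over ± 3-day windows around each
assessment:

    pct_home = 100 · (stay minutes at home ID in window) / (all labeled stay minutes in window)

**Outcomes.** Percent improvement `100 · (baseline − post) / baseline`;
Shapiro–Wilk normality screen with a log-transform rule; Pearson
correlations of quantity and `ln ḡ` with improvement; OLS regression
`improvement ~ quantity + ln ḡ` with t-based 95% CIs; pooled
severity-vs-time-at-home correlation (3 pairs per participant) with a
6000-iteration single-timepoint resampling robustness check.

**Synthetic cohorts.** `generate_cohort()` produces seeded, byte-reproducible
cohorts with planted effect sizes (default `corr(ln ḡ, improvement) = −0.6`,
`corr(time at home, severity) = +0.5`), heavy-tailed bursty usage, 60%
day-level GPS missingness at 15-min sampling, and a home-to-outside shift in
where the app is used — so the whole pipeline is testable without any
participant data.

## Worked example

```r
library(passivecbt)

cfg    <- cohort_config(n_participants = 10, seed = 7)
cohort <- generate_cohort(cfg)
cohort
#> <synthetic_cohort> 10 participants, 84 days, seed 7
#>   usage events: 2447 | GPS fixes: 31680 | assessments: 30

sessions <- filter_outlier_sessions(merge_into_sessions(cohort$events))$kept
duration_histogram(sessions)
#> # A tibble: 5 × 3
#>   bin      count   pct
#>   <chr>    <int> <dbl>
#> 1 (0,5]      955  66.4
#> 2 (5,10]     292  20.3
#> 3 (10,20]    149  10.4
#> 4 (20,40]     37   2.6
#> 5 (40,Inf)     6   0.4

feats <- engagement_features(sessions, treatment_window("full"), cfg$origin_date)
head(feats[, c("participant_id", "quantity_min", "mean_gap_min", "log_mean_gap", "days_used")], 4)
#> # A tibble: 4 × 5
#>   participant_id quantity_min mean_gap_min log_mean_gap days_used
#>   <chr>                 <dbl>        <dbl>        <dbl>     <int>
#> 1 P001                   705.         941.         6.85        64
#> 2 P002                  1129.         541.         6.29        74
#> 3 P003                   497.         972.         6.88        61
#> 4 P004                   393.        1322.         7.19        53

stays <- anonymize_stays(detect_stays(cohort$fixes), seed = 7)
homes <- infer_home(stays)
mob   <- mobility_features(stays, homes, cohort$assessments, cfg$origin_date)
severity_home_correlation(cohort$assessments, mob)
#> $r
#> [1] 0.2330057
#> $p_value
#> [1] 0.2421506
#> $n
#> [1] 27
```

Most synthetic sessions are ≤ 5 min (66.4% here); quantities and log-gaps
sit on the scale of the emulated trial. The pooled severity/home-time
correlation is planted at +0.5, but at n = 10 participants (27 usable
pairs; three windows lacked GPS) a single cohort estimate is very noisy —
here 0.23. Averaged over 50 replicate cohorts of n = 100 the pipeline
recovers both planted correlations to within ±0.1 (see the test suite).

The end-to-end runner reads a cohort directory and writes a report bundle
(`table1.csv`, `daily_usage.csv`, `severity_home_pairs.csv`,
`report.json`):

```r
run_pipeline(run_config(input_dir = "cohort/", output_dir = "out/", seed = 7))
```

A thin CLI wrapper with `generate` / `run` / `report` subcommands lives in
`inst/cli/passivecbt.R`.

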
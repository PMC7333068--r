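Package: passivecbt
Title: Passive Smartphone Engagement and Mobility Analytics for
    App-Delivered CBT
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for passively collected smartphone data from
    app-delivered cognitive behavioral therapy (CBT) trials. Converts raw
    app-usage event logs into burst-merged, outlier-filtered sessions;
    derives engagement features (quantity, frequency, days used, session
    duration histograms, daily usage series); turns GPS fix logs into
    anonymized stay intervals, infers the home location from night-time
    observations, and computes percent time at home around clinical
    assessments as a candidate digital marker of avoidance; and runs the
    outcome statistics (percent symptom improvement, normality screening,
    Pearson correlations, two-predictor regression, and a single-timepoint
    resampling robustness check). A seeded synthetic-cohort generator with
    planted effect sizes makes every stage testable without access to raw
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    geosphere,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
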
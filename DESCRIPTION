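Package: hazgaze
Title: Time-to-Fixate Extraction and Group Statistics for
    Driving-Simulator Hazard Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes time-to-fixate (TTF) and companion hazard-perception
    features from per-frame object detections, scene-camera gaze samples and
    driving-simulator logs. Assembles pedestrian (person-class) detection
    tracks, locates hazard onset and the first gaze sample falling inside the
    hazard's bounding rectangle, and derives initial gaze distance, speed at
    onset, time-to-collision and brake-based perception response times.
    Applies session-level quality control (frozen gaze, missing samples,
    recording pauses, anticipatory perception) and cohort-level validity and
    interquartile-range outlier screening, then runs the group-comparison
    battery (Welch's ANOVA, Tukey HSD, sequential-SS general linear model with
    covariates, Shapiro-Wilk residual checks, Pearson correlations). Includes
    deterministic synthetic session and cohort generators with known ground
    truth so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
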
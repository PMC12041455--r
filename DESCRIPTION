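Package: meafish
Title: Microelectrode-Array and Locomotor Seizure Metrics for Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for characterizing seizure-like
    hyperactivity in larval zebrafish from in vivo microelectrode-array (MEA)
    recordings and locomotor trajectories. Provides RMS-adaptive spike
    detection on band-pass filtered extracellular voltage traces, ISI-based
    burst and network-burst detection, active-electrode classification and
    weighted mean firing rate, swim-trajectory metrics (distance, velocity,
    rotation events, mobility, dark/light phase bins), the group-comparison
    statistics used in this field (Welch t, Welch and Brown-Forsythe one-way
    ANOVA, two-way ANOVA with Tukey HSD, repeated-measures one-way ANOVA,
    ROUT outlier removal), and a synthetic-data generator with full ground
    truth for control, crispant-like and PTZ-like scenarios so every stage is
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
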
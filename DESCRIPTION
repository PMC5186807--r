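Package: drivescore
Title: Rule-Based Driving-Error Detection and Simulator-Training Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Offline re-implementation of a driving-simulator training
    evaluation pipeline for cognitively impaired older drivers. Provides a
    reference 27.48-km training scenario with speed zones, intersections and
    lane-change prompts; a rule-based detection engine for eight classes of
    driving error (speeding, tailgating, weaving, turn-signal and blind-spot
    omissions at lane changes, stop-sign control, visual search at stop signs,
    and red-light control) with explicit thresholds, re-warning windows and a
    feedback refractory period; a synthetic driver-cohort generator that
    emulates learning across five training sessions and loss of retention at a
    six-month recall; and the nonparametric repeated-measures statistics
    (Friedman, Wilcoxon signed-rank, two-sample Kolmogorov-Smirnov) used to
    quantify the training effect, each with exact small-sample modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
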
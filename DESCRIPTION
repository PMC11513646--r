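Package: sociomove
Title: Energy, Movement and Social Opportunity Analysis for Group-Living Animals
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to link energy availability, movement and sociality in
    group-living animals tracked with high-resolution GPS. Computes daily
    movement metrics (total travel distance, step length, sinuosity,
    residence time) from fix tables, detects dyadic close-proximity "social
    opportunity" events, processes lagged faecal thyroid-hormone (fT3)
    covariates with within-/between-individual decomposition, summarises
    sunrise-to-sunset grooming durations, and fits the chained linear
    mixed-model suite relating the three data streams. Includes an
    agent-based cohesive-group movement simulator with known ground-truth
    effects for end-to-end parameter-recovery and type-I-error studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Config/testthat/parallel: false
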
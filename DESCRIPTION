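Package: torpr
Title: Detection of Nocturnal Daily Torpor from Nest Temperature and
    Whole-Nest Respirometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-signal pipeline for detecting nocturnal daily torpor in
    nest-resting bird families. Detects substantial nest-temperature drops
    against an ambient-referenced criterion with a torpor-cycle shape
    requirement, scores whole-nest metabolic-rate reduction from
    indirect-calorimetry (oxygen-consumption) traces, aggregates events
    into per-season summaries, times torpor bouts against computed sunset
    and sunrise, and fits mixed-model ambient-temperature contrasts.
    Includes a synthetic-data generator (diel ambient forcing, Newtonian
    nest thermal model, arrival-peak and torpor-bout gas-exchange traces)
    with known ground-truth labels for validating the detectors.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
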
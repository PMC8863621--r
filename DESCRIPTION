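Package: beamaudit
Title: Beam-Model Parameter Audits for Radiotherapy Phantom Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing treatment-planning-system (TPS) beam-model
    parameters against community survey distributions. Scores an
    institution's reported parameters as community percentiles, flags
    atypical values (outer 20 percent of the survey), predicts the
    resulting systematic dose-calculation error with a piecewise-linear
    per-parameter effect model aggregated additively, classifies phantom
    dosimetry audits (TLD dose errors, film gamma pass rates, localization
    exclusion), and tests associations between atypical modeling and audit
    failure. Includes a synthetic study generator that emulates community
    parameter distributions and phantom-audit cohorts so the full pipeline
    is testable without access to proprietary audit databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
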
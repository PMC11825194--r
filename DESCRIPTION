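Package: persistkit
Title: Treatment Persistence and Dose-Optimization Analysis for Infliximab
    Therapeutic Drug Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives treatment persistence from longitudinal infusion records
    using a grace-period gap rule, detects dose-optimization events from
    interval and dose-level changes, builds therapeutic drug monitoring (TDM)
    subgroup cohorts, fits stratified Cox proportional-hazards models with
    time-dependent exposure (counting-process format, avoiding immortal-time
    bias), and runs tipping-point quantitative bias analysis.  Ships a
    synthetic patient-support-program data generator with known ground truth
    so every stage of the pipeline is testable without access to real
    administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
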
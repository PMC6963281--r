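Package: copdwatch
Title: Rule-Based Telemonitoring Engine for COPD Patients
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: A native, testable implementation of a personalized rule-based
    clinical decision support system for the remote monitoring of patients
    with chronic obstructive pulmonary disease (COPD). Provides typed patient
    medical profiles with per-activity safe bands for eleven vital signs,
    closed-form ambient-physiology equations (hypsometric pressure, gas
    partial pressures, altitude arterial oxygen regression, ambient
    temperature effects on heart rate and blood pressure, cold-driven lung
    function decline), indoor air quality index computation, declarative
    rulepacks with temporal exposure windows and exposure-dependent dynamic
    thresholds, a streaming alarm engine, a Markov-chain activities-of-daily
    -living simulator with profile-conditioned vital signs and environmental
    time series, and confusion-matrix evaluation of alarm quality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
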
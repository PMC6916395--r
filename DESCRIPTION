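Package: jmie
Title: Joint Models for Longitudinal and Time-to-Event Data with
    Intermediate Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint modeling of a longitudinal biomarker and a survival
    endpoint when an intermediate event (reintervention, serious adverse
    event) can change both the biomarker trajectory and the instantaneous
    risk during follow-up. Provides a change-point mixed-effects
    longitudinal submodel with a level drop and slope change (or a
    post-event B-spline) at the intermediate event, a relative-risk
    survival submodel with the intermediate-event indicator as a binary
    time-varying covariate and association structures (current value,
    slope, area) that may switch at the event, Bayesian estimation by
    Markov chain Monte Carlo, scenario-adaptive individualized dynamic
    survival predictions, intermediate-event-stratified time-dependent
    AUC and expected prediction error estimators, and a simulation engine
    for biomarker-triggered intermediate events with hazard-inversion
    event times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    survival,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    flexsurv
Config/testthat/edition: 3
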
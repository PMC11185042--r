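Package: pursuitlink
Title: Saccade-Smooth-Pursuit Interaction Analysis for Step-Ramp Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the interaction between saccades and smooth
    pursuit eye movements in step-ramp (Rashbass) tracking tasks sampled at
    1 kHz. Provides a synthetic step-ramp gaze simulator with known latent
    parameters (pursuit latency, pre- and post-saccadic gain, two-target
    selection weights), robust eye-velocity estimation (25 ms median filter
    followed by dual-rate differentiation), peri-saccadic window measures and
    trial-inclusion rules, bootstrapped threshold-linear pursuit-latency
    fitting, vector-decomposition target-selection weights for saccades and
    pursuit, and ROC choice-probability statistics with bootstrap confidence
    intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
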
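Package: kayakforce
Title: Leg Push Force Analysis and Velocity Modelling for On-Water Sprint Kayaking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing dual-channel (left/right) footrest force
    recordings from sprint kayaking. Provides zero-phase Butterworth
    filtering, per-side push-peak detection, left-anchored stroke-cycle
    segmentation and time-normalized ensemble force profiles; computes the
    five classic leg-force characteristics (stroke rate, mean force, peak
    force, impulse per stroke cycle, impulse over 10 s); and fits
    explanatory and predictive linear models of paddling velocity with
    BIC subset selection, k-fold cross-validation, case-resampling
    bootstrap confidence intervals and residual diagnostics. A synthetic
    session and cohort generator with closed-form ground truth makes the
    whole pipeline testable without access to athlete data.
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
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
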
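Package: pointseq
Title: Sequential Analysis of Toddler Pointing in Caregiver-Toddler Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for observational sequential analysis of time-stamped
    behavioral codings from caregiver-toddler dyads. Builds per-session 2x2
    contingency tables linking the momentary caregiver activity category to
    toddler pointing, computes adjusted-residual z-scores, quantifies the
    temporal coupling of toddler face-looks with pointing within a two-second
    window, and tests category associations and developmental-period effects
    with one-sample t-tests and linear mixed-effects models with per-toddler
    variance strata. Includes a semi-Markov simulator of caregiver-toddler
    mealtime sessions for power analysis, calibration checks, and fully
    reproducible end-to-end pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
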
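Package: devfc
Title: Developmental Change in Functional Brain Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying adolescent maturation of resting-state
    functional connectivity (FC) in accelerated-longitudinal cohorts.
    Provides head-motion quality control (framewise displacement, scan
    exclusion, QC-FC diagnostics, FD regression, global signal
    regression), wavelet bandpass filtering of regional time series,
    Pearson FC matrices and weighted-degree network summaries, per-edge
    random-intercept mixed-effects growth models (baseline connectivity
    at age 14 and linear change to age 26), the per-region Maturational
    Index with parametric and spin-permutation significance,
    conservative/disruptive mode classification, spatial colocation of
    the Maturational Index map with annotation maps under spin nulls,
    and a synthetic-cohort generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
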
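Package: cardiosleep
Title: Sleep Staging and Sleep-Quality Classification from Single-Lead Cardiac Cycle Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing overnight single-lead cardiac cycle (RR-interval)
    recordings. Implements heart-rate-variability feature extraction (time-domain,
    spectral, detrended fluctuation analysis, sample and fuzzy entropy, Poincare
    and time-irreversibility statistics), four-class sleep staging
    (wake / REM / light / deep) via per-stage recognizers built from dually
    smoothed principal-component curves with variable-threshold boundary
    correction and probabilistic multi-classifier fusion, and a downstream
    good/poor sleep-quality classifier driven by hypnogram structure. A synthetic
    night and cohort generator makes the whole pipeline testable without
    polysomnography data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    e1071,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
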
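Package: actidx
Title: Actigraphy Feature Extraction and Diagnostic Classification for Dementia Etiologies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for week-long body-worn actigraphy in memory-clinic
    populations. Ingests epoch-level activity-category and intensity-count
    exports, aggregates them to clock-aligned 15-minute windows, computes
    nonparametric circadian indices (intra-daily variability, M10/L5 with
    timing, relative amplitude) and activity-composition features over
    clinically motivated clock periods, and classifies dementia etiologies
    (Alzheimer's disease, dementia with Lewy bodies, cerebrovascular disease)
    against healthy controls with an mRMR-filtered sequential-forward-selection
    logistic classifier evaluated in nested leave-one-out cross-validation,
    reporting exact-binomial (Clopper-Pearson) confidence intervals. Includes a
    seeded synthetic cohort generator emulating group-level rest-activity
    structure so the full pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
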
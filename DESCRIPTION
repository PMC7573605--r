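Package: hemovalid
Title: Agreement and Trending Statistics for Continuous Hemodynamic
    Monitor Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for validating a continuous hemodynamic
    monitor against invasive reference measurements (arterial line,
    pulmonary-artery thermodilution): successive-percentage-difference
    outlier screening, per-phase method-comparison statistics (Pearson
    correlation and regression, two-way random-effects absolute-agreement
    intraclass correlation with standard error of measurement,
    Bland-Altman bias and 95% limits of agreement, Critchley percentage
    error, blood-pressure error bins), and four-quadrant trending
    concordance with exclusion zones. Includes a synthetic-cohort
    generator that emulates a three-phase controlled hemorrhagic-shock
    protocol (pre-bleeding, bleeding, post-bleeding) so the full pipeline
    is exercisable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    nortest,
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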
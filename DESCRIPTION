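Package: rbcmech
Title: Single-Cell AFM Mechanics of Red Blood Cells and Case-Control
    Biomarker Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for atomic force microscopy (AFM) force-distance
    spectroscopy of red blood cells. Converts raw approach/retract cycles to
    force versus indentation, fits the Sneddon conical-contact model for the
    apparent Young's modulus, and extracts the large-indentation stiffness
    slope, dissipated energy, hysteresis and work of adhesion from every
    curve. Organizes per-pixel curves into 8x8 elasticity maps, removes bare
    substrate pixels, and aggregates mechanics per cell and per patient.
    A cohort statistics layer provides case-control marker summaries
    (Wilcoxon, Fisher, chi-square), DeLong ROC-AUC with confidence intervals
    and curve comparison, bivariate logistic marker models with stepwise AIC
    selection and leave-one-out cross-validation, power-filtered Spearman
    correlation matrices, and bootstrap Cullen-Frey skewness-kurtosis
    analysis. A seeded synthetic-data generator produces physically
    structured curves, cell maps and calibrated two-group cohorts with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    boot,
    e1071,
    fitdistrplus,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
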
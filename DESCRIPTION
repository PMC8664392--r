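Package: qusrad
Title: Quantitative Ultrasound Radiomics with Texture Derivatives for
    Recurrence Risk Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantitative ultrasound
    (QUS) radiomics of tumour radiofrequency (RF) echo data. Implements
    reference-phantom normalized spectral parameter estimation (mid-band
    fit, spectral slope and intercept, scatterer spacing, effective
    scatterer diameter and acoustic concentration, attenuation coefficient
    estimate), gray-level co-occurrence matrix (GLCM) texture features of
    parametric maps and second-pass texture derivatives, assembly of the
    95-feature patient catalog, normality-routed univariate group
    comparisons, balanced forward-selection KNN and SVM classification
    under leave-one-out cross-validation, and Kaplan-Meier/log-rank
    survival stratification of predicted recurrence groups. Includes a
    point-scatterer RF frame simulator and outcome-labelled cohort
    generator with known ground truth so the full pipeline is testable
    without clinical scans.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    class,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
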
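Package: radonset
Title: CT Radiomics Modelling of Time from Stroke Onset
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating a CT-radiomics classifier of
    time from stroke onset (within versus beyond the 4.5-hour intravenous
    thrombolysis window) in middle cerebral artery occlusion. Provides a
    seeded synthetic cohort and CT-like phantom generator, volume
    preprocessing (isotropic resampling, intensity windowing, gray-level
    discretization), a 396-feature radiomics extractor (histogram, shape,
    Haralick, co-occurrence, run-length and size-zone families), a
    feature-selection cascade (univariate filtering, Spearman redundancy
    elimination, cross-validated LASSO), rad-score and combined
    clinicoradiological logistic models, and an evaluation suite (DeLong
    ROC analysis, McNemar and Hosmer-Lemeshow tests, intraclass correlation,
    decision-curve analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    igraph,
    pROC,
    jsonlite,
    RNifti
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
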
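Package: canopyLAI
Title: Maize Canopy Leaf Area Index Estimation from Multispectral Plot
    Imagery with Texture Indices and Stacked Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates crop canopy leaf area index (LAI) from five-band
    (blue, green, red, red-edge, near-infrared) plot reflectance imagery.
    Implements vegetation indices, gray-level co-occurrence matrix (GLCM)
    texture features computed with a compiled sliding-window engine,
    two- and three-component texture indices with combinatorial candidate
    enumeration and correlation ranking, Pearson screening applied inside
    training folds, and stacked ensemble regression coupling partial least
    squares with support vector, random forest or gradient boosting base
    learners through out-of-fold meta-features and a Lasso meta-model,
    evaluated by nested cross-validation. A synthetic canopy scene
    generator based on a two-endmember Beer-Lambert gap-fraction model
    provides ground-truthed imagery for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    mixOmics,
    e1071,
    ranger,
    xgboost,
    glmnet,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
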
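Package: ehrshift
Title: Temporal Dataset Shift Characterization and Its Association with
    Predictive Model Performance in Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised characterization of temporal dataset shifts in
    admission-level electronic health record data and association of those
    shifts with interyear predictive-model performance. Provides data
    temporal heatmaps (DTHs) for marginal, prior, class-conditional and
    posterior distributions; information-geometric temporal (IGT)
    projections via Jensen-Shannon dissimilarity and classical
    multidimensional scaling; factorial analysis of mixed data with
    per-year kernel density maps; yearly random-forest and
    gradient-boosting model grids with Youden-index thresholding and
    interyear evaluation matrices; and cluster-association testing with
    the Fisher exact test under false discovery rate control. Includes a
    synthetic EHR cohort generator with controllable covariate, prior and
    concept shifts and an ICD-9 to ICD-10 style coding-system transition,
    so the full pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    withr,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
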
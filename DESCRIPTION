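Package: fluidQDA
Title: Body-Fluid Classification from miRNA RT-qPCR Panels by Quadratic
    Discriminant Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forensic identification of human body fluids (blood, menstrual
    secretions, feces, urine, saliva, semen, vaginal secretions) from a
    seven-miRNA RT-qPCR expression panel normalized to the let-7g/let-7i
    endogenous references. Implements delta-Cq computation from technical
    replicates, single imputation of missing markers by the conditional
    multivariate-normal mean, augmentation of the training set with a
    synthetic "Other" rejection class drawn outside the 3.5-standard-deviation
    Mahalanobis ellipsoid, quadratic discriminant classification with a
    posterior confidence gate, stratified 10-fold cross-validation with
    per-fluid rate tables, and a synthetic-data generator emulating the
    statistical structure of population qPCR panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
biocViews: Classification, qPCR, GeneExpression, Transcriptomics
RoxygenNote: 7.3.3
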
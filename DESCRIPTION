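Package: splenometrics
Title: Automated Spleen Laceration Detection from CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects traumatic spleen lacerations in abdominal CT volumes
    from quality-controlled spleen segmentations. Extracts per-slice
    histogram statistics (including Renyi entropy), Gabor filter-bank
    texture features, box-counting fractal dimensions of the segmentation
    perimeter and area, and contour shape descriptors, then classifies
    healthy versus lacerated spleens with classical machine-learning models
    (random forest, naive Bayes, SVM, k-NN and subspace-discriminant
    ensembles) under stratified cross-validation, held-out testing,
    per-grade and leave-one-site-out evaluation. Includes a synthetic
    phantom generator so the full pipeline can be exercised without
    protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    MASS,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    pROC,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
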
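Package: rawms
Title: Raw SWATH-MS Spectra as Images for Transfer-Learning Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts raw data-independent-acquisition (SWATH-MS) runs into
    fixed-size intensity images by binning points over retention time and
    mass-to-charge, encodes those images into feature vectors through a
    pluggable encoder interface, and benchmarks binary phenotype classifiers
    (logistic regression, support vector machines, random forests, gradient
    boosted trees) under a seeded stratified split with repeated
    cross-validated grid search selected on AUC. Includes a synthetic SWATH
    cohort generator with Gaussian elution profiles, isolation-window fragment
    routing and configurable class effect sizes, so the full pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mzR,
    e1071,
    ranger,
    xgboost,
    glmnet,
    png,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
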
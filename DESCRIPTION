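Package: gknn
Title: Generalized k-Nearest-Neighbor QSAR Models of Chemical Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-linear k-nearest-neighbor estimation of continuous
    chemical activity scores from molecular similarity. Implements the
    generalized kNN (GkNN) estimator, a similarity-weighted power mean of
    neighbor activities with separate non-linearity exponents for the
    activity and structure spaces, together with the classical arithmetic,
    geometric and exponential-weighting kNN variants. Includes Tanimoto
    fingerprint similarity (circular, path-based and MACCS backends),
    structure-activity landscape (SALI) diagnostics for activity cliffs,
    kernel eigenprojection of chemical space, confidence scoring by
    nearest-training-set similarity, threshold classification metrics with
    a composite ranking score, leave-one-out cross-validation with a full
    (k, x, y) parameter grid search, and a seeded synthetic-data generator
    for smooth, cliff-bearing and random activity landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    graphics,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
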
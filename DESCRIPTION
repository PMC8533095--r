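Package: pdxomc
Title: Optimal Model Complexity Random Forests for PDX Drug-Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for predicting in vivo drug response of patient-derived
    xenografts (PDXs) from tumour molecular profiles. Encodes gene-level SNV,
    copy-number and expression tables into model-ready feature matrices,
    classifies mRECIST-style treatment response from tumour-volume curves,
    and benchmarks class-weighted random forests against a feature-count
    selection variant (RF-OMC) chosen by nested leave-one-out
    cross-validation, single-gene mutation markers ranked by Fisher's exact
    test, and random baselines, with Matthews-correlation-centred evaluation.
    Includes a synthetic PDX cohort generator with planted response-associated
    features so the full pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
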
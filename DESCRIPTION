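Package: prolifindex
Title: Pan-Cancer Proliferative Index and Survival Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Computes a PCNA meta-gene proliferative index (PI) from bulk
    RNA-seq counts and analyzes its role across cancers: per-cancer Cox
    survival associations for the PI and for every transcript,
    classification of proliferation-informative cancers (PICs) with
    Bonferroni correction and a Ward-clustering consistency check,
    cross-cancer extreme-survivor classifiers (LASSO, ridge, random forest,
    linear SVM) with a random-cancer-set permutation null, and associations
    of PI with somatic mutation burden, per-gene mutation status, drug EC50s
    and Connectivity-Map-style treatment rank matrices. Ships a synthetic
    multi-cancer cohort generator with planted ground truth so every stage
    is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    survival,
    utils
Suggests:
    e1071,
    jsonlite,
    pROC,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
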
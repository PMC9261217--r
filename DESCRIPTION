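Package: weaklabelr
Title: Weak Supervision for Lifestyle-Status Sentence Classification in
    Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying weak supervision on lifestyle-status
    sentence classification in clinical notes. Provides sentence-level
    preprocessing (splitting, normalisation, deduplication), a rule-based
    weak labeler for physical-activity and excessive-diet status that
    scans keyword phrases and a fixed token window before each match for
    negation and prospective triggers, a template-based synthetic corpus
    generator with gold labels and full generation traces, TF-IDF n-gram
    baseline classifiers (logistic regression, linear SVM, random
    forest) behind a pluggable text-classifier contract, seed-averaged
    evaluation with per-class and weighted metrics, and an end-to-end
    experiment driver including a weak-data-proportion ablation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    glmnet,
    jsonlite,
    Matrix,
    methods,
    randomForest,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
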
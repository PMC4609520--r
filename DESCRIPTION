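Package: tcmensemble
Title: Selective Deep Ensembles for ICD-10 Annotation and Acupoint Recommendation
Version: 0.1.0
Authors@R:
    person("TCM", "Ensemble Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Selective deep-ensemble learning for multi-output clinical
    coding of Traditional Chinese Medicine (TCM) records. Pools of bootstrap
    decision-tree and margin-based base learners are scored by a tuple
    accuracy and a vote-distance diversity, ranked by nondominated sorting,
    and combined either by top-b% majority voting or by capacity-regularized
    boosting weights, to annotate single ICD-10 labels and recommend
    acupuncture points (53-way multi-label) from featurized clinical records.
    Includes a seeded synthetic clinical-record generator, keyword-matching
    featurization, repeated ten-fold evaluation under zero-one and Hamming
    losses, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
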
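Package: ordlink
Title: Ordered Message-Passing Link Prediction for Microbe-Drug
    Association Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts unobserved drug-microbe associations from a binary
    association matrix and optional curated similarity matrices. Fuses
    Gaussian interaction profile kernel similarities with curated
    similarities into a heterogeneous network, encodes it with a deep
    ordered message-passing graph neural network whose monotone
    per-feature gates counter over-smoothing, and scores pairs with a
    bilinear decoder under a class-balanced cross-entropy loss. Includes
    the repeated five-fold cross-validation protocol with negative
    sampling, a paired mean-aggregator ablation baseline, a
    hyperparameter sweep harness, a synthetic low-rank world generator,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
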
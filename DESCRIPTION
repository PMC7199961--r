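Package: mircnn
Title: Predicting miRNA Target Sites from Raw Chimeric Sequences with a
    Convolutional Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds miRNA:target-site chimera datasets from interaction
    records, trains a small one-dimensional convolutional neural network
    directly on one-hot encoded RNA sequence, and predicts miRNA targeting
    of full-length transcripts by scanning candidate sites, filtering them
    on the minimum free energy of the miRNA:site duplex, scoring survivors
    with the trained network and aggregating by the maximum site score.
    Includes a nearest-neighbor duplex energy model, the standard binary
    classification metrics (sensitivity, specificity, F1, Matthews
    correlation, accuracy) with ROC/AUC, k-fold cross-validation, and a
    seeded synthetic-data generator that plants seed-complementary target
    sites so every stage of the pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
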
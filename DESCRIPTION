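Package: capsddi
Title: Multimodal Capsule-Network Prediction of Drug-Drug Interaction Types
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts the pharmacological type of drug-drug interactions
    (DDIs) by fusing four drug-pair feature modalities through a capsule
    network with dynamic routing. Per-drug features are knowledge-graph
    embeddings (TransE pretraining refined by a reweighted graph
    convolution), concatenated molecular fingerprints (MACCS, ECFP,
    atom-pair and an ErG-style reduced-graph pharmacophore fingerprint),
    molecular-graph embeddings from a four-layer edge-featured graph
    attention encoder with shared deep-layer weights, and binary
    enzyme/target pharmacology vectors. Pair-level vectors are projected,
    squashed and routed through a two-layer capsule network; a three-layer
    perceptron head performs multiclass or multilabel classification.
    Includes composable dataset-construction filters, a seeded synthetic
    data generator so the whole pipeline runs at desk scale, stratified
    cross-validated training with Adam, and standard evaluation metrics
    (micro AUPR/AUC, Cohen's kappa, accuracy, macro-precision).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
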
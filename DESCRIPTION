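Package: aidnet
Title: Hybrid Convolutional-Recurrent Networks with Graph Topology
    Refinement for Autoimmune Disorder Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-class diagnosis of autoimmune disorders from tabular
    clinical records using a hybrid deep network that stacks 1-D
    convolutional feature extraction, a gated recurrent (LSTM/GRU) stage,
    and a graph-based feature-topology refinement layer fused into a
    softmax head.  Ships the full study protocol around the model: a
    seeded synthetic patient-cohort generator with plantable
    class-conditional biomarker signal, a leakage-free preprocessing
    pipeline (train-fitted imputation, min-max scaling, one-hot encoding,
    z-score winsorization, stratified 80/10/10 splitting, SMOTE
    oversampling), cross-entropy training with Adam or SGD-with-momentum,
    Xavier initialization and early stopping, multi-class metrics
    (macro precision/recall/F1, one-vs-rest AUC-ROC and AUC-PR), a
    baseline-comparison harness with paired t-tests and 95% confidence
    intervals, a six-variant ablation suite, and model-agnostic
    permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    randomForest,
    nnet,
    class,
    yaml,
    optparse
Config/testthat/edition: 3
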
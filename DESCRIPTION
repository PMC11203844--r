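Package: conformxplain
Title: Explainable Classification of GPCR Conformational States under
    Class Imbalance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to classify receptor conformational states (active,
    intermediate, inactive) from residue-level molecular dynamics
    trajectories and to explain the classifier's decisions at residue
    resolution. Includes a seeded synthetic-trajectory generator with
    planted state-informative residues, center-of-mass featurization and
    marker-distance labeling, from-scratch implementations of six class
    imbalance mitigation strategies (SMOTE, ADASYN, SMOTEENN, NearMiss,
    random over/under-sampling, class-weighted loss), a compact 1D
    convolutional network with decision-tree and random-forest baselines,
    four attribution methods (layer-wise relevance propagation, gradient
    saliency, LIME-style surrogates, Kernel SHAP), and an assessment layer
    covering imbalance-aware metrics (MCC, one-vs-all AUC), explanation
    robustness and stability via cosine similarity, interquartile-range
    relevance filtering and cross-method consensus.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    rpart,
    randomForest,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
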
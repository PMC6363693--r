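Package: sweetqsar
Title: Consensus Fingerprint QSAR Models for Sweetener Classification and
    Relative Sweetness Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable toolkit for consensus QSAR modeling of sweet taste.
    Provides a native extended-connectivity fingerprint (ECFP) engine with
    per-bit substructure provenance, Tripos MOL2 and SDF V2000 readers on a
    heavy-atom molecular graph, dataset curation rules for taste-labeled
    compound collections, multi-scheme data splitting, five machine-learning
    method families (k-nearest neighbors on Tanimoto distance, support vector
    machines, gradient boosting, random forests, and small multi-layer
    perceptrons) trained with five-fold cross-validation and random-forest
    feature selection, average and consensus models, Y-randomization
    validation, a Tanimoto-similarity applicability domain, and fingerprint-bit
    model interpretation. A synthetic molecule generator with planted
    structure-label relationships makes the whole pipeline testable without
    external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    randomForest,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
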
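Package: tsmut
Title: Prediction of Temperature-Sensitive Mutations from Sequence and
    Structure Neighborhood Features
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Feature-based prediction of temperature-sensitive (TS) single
    amino-acid substitutions. Computes sequence and structure descriptors of a
    mutation site and of three kinds of residue neighborhood (sequence window,
    Euclidean sphere, Delaunay-topological), fits a class-weighted logistic
    regression classifier with Lasso feature selection via Least Angle
    Regression, and evaluates predictions with accuracy, Matthews correlation,
    Kullback-Leibler divergence, distribution distance, and ROC AUC under
    ten-fold and leave-one-protein-out cross-validation. Includes a synthetic
    structure/alignment/mutation generator so the whole pipeline can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
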
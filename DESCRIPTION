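Package: pssmloc
Title: PSSM-Based Feature Encoding and Imbalance-Aware Classification of
    Protein Subcellular Localization
Version: 0.1.0
Authors@R:
    person("pssmloc", "developers", email = "pssmloc@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting protein subcellular localization from
    evolutionary profiles.  Parses PSI-BLAST ASCII position-specific
    scoring matrices (PSSMs), encodes variable-length proteins into
    fixed-length feature vectors (pseudo-PSSM with sequence-axis lags,
    an improved column-lag variant and three cross-product relatives,
    and a bidirectional cross-correlation descriptor), balances classes
    with SMOTE oversampling followed by edited-nearest-neighbour
    cleaning, and evaluates a grid-searched RBF support vector machine
    under jackknife (leave-one-out) cross-validation with sensitivity,
    specificity, F-measure, Matthews correlation, G-mean and overall
    accuracy.  A synthetic PSSM generator makes every stage testable
    without a sequence database search.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    quadprog,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
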
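Package: dilinet
Title: Stacked Proxy-Endpoint Models for Drug-Induced Liver Injury Prediction
Version: 0.1.0
Authors@R: person("dilinet", "developers", role = c("aut", "cre"),
    email = "dilinet@example.org")
Description: A two-level stacked ("FeatureNet") pipeline for predicting
    drug-induced liver injury (DILI) from chemical structure. Level-1
    random-forest models are trained on nine binary proxy-DILI endpoints
    (in vitro and in vivo liver-toxicity assays) and two plasma-Cmax
    regression targets; their predictions are combined with structural
    fingerprints (Morgan + MACCS), bulk 2D molecular descriptors, and
    15 physicochemical parameters to train a level-2 DILI classifier with
    a Youden-J calibrated decision threshold. Includes SMILES
    standardization and pH-7 protonation, variance-threshold feature
    selection, Butina scaffold-aware splitting, repeated nested
    cross-validation, a full metric panel with positive-likelihood-ratio
    detection curves, per-compound tree-path feature attribution, and a
    synthetic multi-endpoint fixture generator with planted
    structure-activity signal. Chemistry primitives are delegated to a
    bundled RDKit batch backend.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with RDKit available as 'python' on PATH
RoxygenNote: 7.3.3
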
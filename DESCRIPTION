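Package: tpascreen
Title: Interpretable Machine Learning for Two-Photon Absorption Cross Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts and explains two-photon absorption cross sections (TPACS,
    in Goeppert-Mayer units) of organic chromophores from SMILES. Provides
    fragment-count featurization (canonicalized atom-centred environments up to
    radius 4), fragment-aggregated atomic properties (Gasteiger PEOE charges,
    additive logP and molar refractivity contributions), bespoke conjugation
    descriptors (conjugation length, branch ratio, conjugated weight and
    surface area, donor-acceptor ratio), a three-model feature-selection
    cascade (lasso, two gradient-boosting flavours) with backward elimination
    and forward stepwise search, repeated random-split cross-validation of
    pluggable regressors in lg(TPACS) units, exact tree-path SHAP attribution
    with power-law extraction for the conjugation length, accumulated local
    effects, and a synthetic chromophore generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    glmnet,
    xgboost,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
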
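Package: rxnaudit
Title: Predictability Audits for Organic Reaction Outcome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit how predictable organic reaction outcomes (yield,
    reaction time) are from standard molecular representations, and whether the
    residual misclassification error is reducible or intrinsic to the
    representation. Builds three feature families for reaction SMILES records
    (whole-molecule descriptor blocks with reaction conditions, signed atom-pair
    reaction-difference fingerprints with hash folding, and chemical-linguistic
    descriptors mined as frequent maximum common substructures), trains random
    forest, extremely randomized tree and LASSO-logistic classifiers under
    stratified four-fold cross-validation, and brackets the Bayes (irreducible)
    classification error with nearest-neighbor Cover-Hart bounds. Includes
    synthetic reaction generators with analytically known Bayes error for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: OpenBabel (obabel on the PATH)
Imports:
    Rcpp,
    ranger,
    glmnet,
    jsonlite,
    yaml,
    digest,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    class,
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
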
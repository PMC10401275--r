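Package: hybfact
Title: Hybrid Yield Prediction in Unbalanced Testcross Factorials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prediction of hybrid performance in incomplete, unbalanced
    two-group testcross factorials, as they arise in newly established
    hybrid breeding programs. Implements combining-ability BLUP for the
    GCA/SCA mixed model on adjusted entry means, genomic BLUP with
    VanRaden relationship matrices and a Kronecker-product SCA kernel
    fitted by REML, parentage-, cross-yield- and marker-based predictor
    encodings for machine-learning regressors (gradient boosting, random
    forest, support vector regression, Gaussian multi-kernel ridge,
    matrix factorization), random grid search with 10-fold
    cross-validation, stacked ensembles of gradient boosting machines
    with a ridge super learner, a cross-validation benchmark harness
    with parent filtering and leakage guards, and a synthetic factorial
    generator with linked inbred-parent marker panels for testing the
    whole pipeline without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    lme4,
    xgboost,
    ranger,
    e1071,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
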
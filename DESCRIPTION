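Package: clinformer
Title: Transformer Models for Survival Prediction on Tabular Clinicogenomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An explainable transformer framework for right-censored survival
    prediction on tabular clinical and genomic cohorts. Patient records are
    treated as unordered sets of (feature name, value) pairs, embedded without
    positional encoding, and encoded by a multi-head self-attention network
    trained with a differentiable sigmoid approximation of Harrell's
    concordance index. Supports masked-feature self-supervised pretraining
    with gradual and transfer learning, embedding-based explainability
    (permutation importance, cosine-similarity functional groups, Cox
    proportional-hazards distillation), generative in-silico feature
    perturbation with variant/invariant population discovery, and a synthetic
    clinicogenomic cohort simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    cluster,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
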
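Package: huangjiuML
Title: Machine-Learning Analysis of the Aging Huangjiu Microbiome and Metabolome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking the aging microbiome of pottery-jar
    huangjiu (Chinese rice wine) to its metabolic profile. Preprocesses paired
    metabolite, physiochemical and taxa-abundance tables (quality filters,
    minimum-value imputation, log10 z-scoring, centered log-ratio transform,
    alpha diversity), assembles named feature groups, predicts each metabolite
    with cross-validated lasso, random-forest and gradient-boosting learners,
    assesses significance of explained variance by bootstrap, and attributes
    predictions to features with directional mean-absolute Shapley values
    computed by a native TreeSHAP implementation. Ships a synthetic-data
    generator with planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    vegan,
    ape,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
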
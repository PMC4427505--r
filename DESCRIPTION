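Package: pkddi
Title: Mining Pharmacokinetic Drug-Drug Interaction Evidence from the Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A literature-mining pipeline for identifying pharmacokinetic
    evidence of drug-drug interactions (DDI) at the abstract and sentence
    level. Reads labeled MEDLINE flat-file and sentence corpora, builds
    Porter-stemmed binary unigram/bigram occurrence matrices with bibliographic
    metadata tokens and dictionary-based named-entity count features, and
    evaluates six linear classifiers (Variable Trigonometric Threshold,
    support vector machine, logistic regression, Beta-smoothed Naive Bayes,
    regularized and diagonal linear discriminant analysis) under repeated
    nested cross-validation. Performance is summarized by F1, Matthews
    correlation, interpolated precision-recall AUC, and their rank product
    (RP3), with exact paired sign-flip permutation tests for configuration
    comparisons. Includes a parametric corpus simulator with known
    class-conditional occurrence probabilities for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
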
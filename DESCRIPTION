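Package: petminer
Title: Identifying Personal Health Experience Tweets with Word Embeddings
    and an LSTM Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining personal health experience tweets (PETs) from
    short social-media text. Implements the full pipeline: corpus filtering
    and tokenisation with data-driven phrase merging, vocabulary construction
    with reserved pad/unk entries, skip-gram negative-sampling word
    embeddings, fixed-length index-sequence encoding, a class-weighted LSTM
    binary classifier trained with weighted cross-entropy and L2
    regularisation, a bag-of-words logistic-regression baseline, and an
    evaluation harness with stratified k-fold cross-validation, the standard
    performance measures, and one-tail paired t-tests between methods. A
    synthetic-corpus generator with controllable class structure makes every
    stage testable without access to live Twitter data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    glmnet,
    Matrix,
    e1071,
    class,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
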
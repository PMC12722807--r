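Package: charRQA
Title: Character-Level Recurrence Embeddings of Speech Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Encodes picture-description speech transcripts (CHAT format) as
    integer character sequences, renders them as symbolic recurrence plots,
    learns a discriminative 128-dimensional embedding with a Siamese
    convolutional encoder trained by contrastive loss, and validates
    embedding discriminability with a gradient-boosted classifier under
    participant-grouped stratified cross-validation with bootstrap
    confidence intervals. Includes a word-level TF-IDF + logistic regression
    baseline under the identical protocol, recurrence quantification
    diagnostics, and a synthetic two-class CHAT corpus generator with
    controllable disfluency contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    stringi,
    jsonlite,
    xgboost,
    glmnet,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
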
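#' TF-IDF configuration
#'
#' @param lowercase fold case before tokenizing (default `TRUE`).
#' @param minDf minimum document frequency for a term to enter the
#'   vocabulary (default 1).
#' @param sublinearTf use `1 + log(tf)` instead of raw term counts
#'   (default `FALSE`).
#' @param ngram n-gram range; only unigrams `c(1, 1)` are supported.
#' @return named list.
#' @export
tfidfConfig <- function(lowercase = TRUE, minDf = 1L, sublinearTf = FALSE,
                        ngram = c(1L, 1L)) {
  stopifnot(minDf >= 1L, length(ngram) == 2L, ngram[1] <= ngram[2])
  if (!identical(as.integer(ngram), c(1L, 1L)))
    stop("only unigram features are supported")
  list(lowercase = lowercase, minDf = as.integer(minDf),
       sublinearTf = sublinearTf, ngram = as.integer(ngram))
}

# glmnet warns whenever a class has < 8 observations, which is routine in
# small inner folds; silence just that warning
quietGlmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

tokenizeWords <- function(texts, lowercase = TRUE) {
  x <- if (lowercase) tolower(texts) else texts
  lapply(strsplit(x, "[^a-z0-9']+"), function(t) t[nzchar(t)])
}

#' Word-level TF-IDF vectorization
#'
#' Term frequency times smoothed inverse document frequency,
#' `idf = ln((1 + n) / (1 + df)) + 1`, with L2-normalized rows. The
#' vocabulary is fit on the supplied (training) texts; a fitted vocabulary
#' can be reused to transform held-out texts, where unseen terms contribute
#' nothing.
#'
#' @param texts character vector of documents.
#' @param config from [tfidfConfig()].
#' @param vocabulary optional fitted vocabulary (list with `terms`, `idf`)
#'   from a previous call; when supplied, `texts` are transformed only.
#' @return list with `matrix` (documents x terms), `terms`, `idf`.
#' @export
tfidfVectorize <- function(texts, config = tfidfConfig(),
                           vocabulary = NULL) {
  if (length(texts) == 0L) stop("empty corpus")
  toks <- tokenizeWords(texts, config$lowercase)
  if (is.null(vocabulary)) {
    df <- table(unlist(lapply(toks, unique)))
    keep <- names(df)[df >= config$minDf]
    if (length(keep) == 0L)
      stop("empty vocabulary after applying min_df = ", config$minDf)
    terms <- sort(keep)
    n <- length(texts)
    idf <- log((1 + n) / (1 + as.numeric(df[terms]))) + 1
  } else {
    terms <- vocabulary$terms
    idf <- vocabulary$idf
  }
  M <- matrix(0, length(texts), length(terms),
              dimnames = list(NULL, terms))
  for (i in seq_along(toks)) {
    tf <- table(toks[[i]])
    tf <- tf[names(tf) %in% terms]
    if (length(tf)) {
      v <- as.numeric(tf)
      if (config$sublinearTf) v <- 1 + log(v)
      M[i, names(tf)] <- v * idf[match(names(tf), terms)]
    }
  }
  norms <- sqrt(rowSums(M^2))
  nz <- norms > 0
  M[nz, ] <- M[nz, , drop = FALSE] / norms[nz]
  list(matrix = M, terms = terms, idf = idf)
}

#' TF-IDF + regularized logistic regression under grouped CV
#'
#' The word-level reference representation evaluated under the identical
#' participant-grouped protocol as the embedding pipeline: per outer fold,
#' the vocabulary and idf weights are fit on training texts only, a ridge
#' logistic model is fit with the regularization strength selected by inner
#' cross-validated AUC, and the held-out fold is scored. The
#' [FoldAssignment-class] can be reused bit-for-bit from the main pipeline.
#'
#' @param corpus a [TranscriptCorpus-class].
#' @param folds a [FoldAssignment-class] (defaults to
#'   `participantFolds(corpus, k, seed)`).
#' @param k outer folds if `folds` is missing.
#' @param seed integer seed.
#' @param config from [tfidfConfig()].
#' @param lambdaGrid ridge penalties searched by inner 3-fold CV AUC.
#' @param B bootstrap resamples for the CI.
#' @return a [CVReport-class].
#' @export
logisticCV <- function(corpus, folds = NULL, k = 5L, seed = 1L,
                       config = tfidfConfig(),
                       lambdaGrid = c(0.01, 0.1, 1, 10), B = 10000L) {
  rec <- corpusRecords(corpus)
  if (is.null(folds)) folds <- participantFolds(corpus, k, seed)
  foldOf <- transcriptFolds(folds, corpus)
  kk <- folds@k
  foldAucs <- numeric(kk)
  for (f in seq_len(kk)) {
    tr <- foldOf != f
    if (length(unique(rec$label[!tr])) < 2L ||
        length(unique(rec$label[tr])) < 2L)
      stop("fold ", f, " has a single class")
    fit <- tfidfVectorize(rec$text[tr], config)
    xTr <- fit$matrix
    xTe <- tfidfVectorize(rec$text[!tr], config,
                          vocabulary = fit[c("terms", "idf")])$matrix
    yTr <- as.integer(rec$label[tr] == "impaired")
    # inner 3-fold AUC to pick the ridge penalty
    innerId <- withSeed(seed * 13L + f,
                        innerFoldIds(rec$label[tr], 3L,
                                     rec$participant_id[tr]))
    innerAuc <- vapply(lambdaGrid, function(lam) {
      aucs <- numeric(0)
      for (g in 1:3) {
        itr <- innerId != g
        if (length(unique(yTr[itr])) < 2L || length(unique(yTr[!itr])) < 2L)
          next
        m <- quietGlmnet(glmnet::glmnet(xTr[itr, , drop = FALSE], yTr[itr],
                                        family = "binomial", alpha = 0,
                                        lambda = lam))
        sc <- as.numeric(stats::predict(m, xTr[!itr, , drop = FALSE],
                                        s = lam))
        aucs <- c(aucs, aucRank(sc, rec$label[tr][!itr]))
      }
      if (length(aucs)) mean(aucs) else NA_real_
    }, numeric(1))
    lam <- lambdaGrid[which.max(innerAuc)]
    m <- quietGlmnet(glmnet::glmnet(xTr, yTr, family = "binomial",
                                    alpha = 0, lambda = lam))
    scores <- as.numeric(stats::predict(m, xTe, s = lam))
    foldAucs[f] <- aucRank(scores, rec$label[!tr])
  }
  makeCVReport(foldAucs, B = B, seed = seed, config = list(
    representation = "tfidf_logistic", k = kk, seed = seed,
    minDf = config$minDf, sublinearTf = config$sublinearTf,
    lambdaGrid = lambdaGrid))
}
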
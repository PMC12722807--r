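#' Participant-grouped, class-stratified fold assignment
#'
#' Every participant is assigned to exactly one of `k` folds, so all of
#' their transcripts travel together (no identity leakage); participants
#' are shuffled within class and dealt round-robin, which keeps per-fold
#' class proportions close to the global proportions.
#'
#' @param corpus a [TranscriptCorpus-class]; each participant must carry a
#'   single class label.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return a [FoldAssignment-class].
#' @export
participantFolds <- function(corpus, k = 5L, seed = 1L) {
  rec <- corpusRecords(corpus)
  byPart <- tapply(rec$label, rec$participant_id, unique)
  mixed <- names(byPart)[lengths(byPart) > 1L]
  if (length(mixed))
    stop("participants with conflicting labels: ",
         paste(mixed, collapse = ", "))
  partLabel <- vapply(byPart, identity, character(1))
  counts <- table(partLabel)
  if (any(counts < k))
    stop("need at least k = ", k, " participants per class; have ",
         paste(names(counts), counts, sep = ":", collapse = ", "))
  fold <- withSeed(seed, {
    out <- integer(0)
    for (lab in sort(unique(partLabel))) {
      ids <- sample(names(partLabel)[partLabel == lab])
      f <- stats::setNames(rep_len(seq_len(k), length(ids)), ids)
      out <- c(out, f)
    }
    out
  })
  new("FoldAssignment",
      fold = stats::setNames(as.integer(fold), names(fold)),
      k = as.integer(k))
}

#' Fold-statistic summary
#'
#' Arithmetic mean, sample (n-1) standard deviation and extremes of the
#' fold-level AUCs.
#'
#' @param foldAucs non-empty numeric vector.
#' @return named list `mean`, `std`, `min`, `max`.
#' @examples
#' summarizeFolds(c(0.949, 0.951, 0.943, 0.982, 0.944))$mean  # 0.9538
#' @export
summarizeFolds <- function(foldAucs) {
  if (length(foldAucs) == 0L) stop("empty fold list")
  std <- if (length(foldAucs) == 1L) {
    warning("single fold: standard deviation undefined, reported as 0")
    0
  } else stats::sd(foldAucs)
  list(mean = mean(foldAucs), std = std,
       min = min(foldAucs), max = max(foldAucs))
}

#' Bootstrap confidence interval for the mean fold AUC
#'
#' Nonparametric percentile bootstrap: the fold AUCs are resampled with
#' replacement `B` times, the mean of each resample taken, and the 2.5th
#' and 97.5th percentiles of the resulting distribution returned as the
#' confidence bounds.
#'
#' @param foldAucs numeric vector of at least 2 values.
#' @param B number of resamples (default 10000, minimum 100).
#' @param seed integer seed.
#' @return named numeric vector `c(ciLow, ciHigh)`.
#' @export
bootstrapCI <- function(foldAucs, B = 10000L, seed = 1L) {
  n <- length(foldAucs)
  if (n < 2L) stop("need at least 2 fold values")
  if (B < 100L) stop("B must be at least 100")
  means <- withSeed(seed, {
    draws <- matrix(sample(foldAucs, n * B, replace = TRUE), nrow = B)
    rowMeans(draws)
  })
  q <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
  c(ciLow = q[1], ciHigh = q[2])
}

makeCVReport <- function(foldAucs, B = 10000L, seed = 1L, config = list()) {
  s <- summarizeFolds(foldAucs)
  ci <- if (length(foldAucs) >= 2L) bootstrapCI(foldAucs, B, seed)
        else c(ciLow = foldAucs, ciHigh = foldAucs)
  new("CVReport", foldAucs = foldAucs, mean = s$mean, std = s$std,
      min = s$min, max = s$max, ciLow = unname(ci[1]),
      ciHigh = unname(ci[2]), config = config)
}

#' Hyperparameter grid for the gradient-boosted classifier
#'
#' Default search space: learning rate (eta) x maximum tree depth x L2
#' regularization (lambda), selected by inner cross-validated AUC.
#'
#' @param eta learning rates.
#' @param maxDepth maximum tree depths.
#' @param lambda L2 regularization strengths.
#' @param nrounds boosting rounds per fit.
#' @param innerK inner CV folds (default 3).
#' @return data.frame grid with attributes `nrounds`, `innerK`.
#' @export
classifierGrid <- function(eta = c(0.05, 0.1, 0.3), maxDepth = c(3, 5, 7),
                           lambda = c(0, 1, 10), nrounds = 60L,
                           innerK = 3L) {
  g <- expand.grid(eta = eta, maxDepth = maxDepth, lambda = lambda)
  if (nrow(g) == 0L) stop("empty hyperparameter grid")
  attr(g, "nrounds") <- as.integer(nrounds)
  attr(g, "innerK") <- as.integer(innerK)
  g
}

xgbFit <- function(x, y01, eta, maxDepth, lambda, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(data = x, label = y01)
  params <- list(objective = "binary:logistic", eta = eta,
                 max_depth = as.integer(maxDepth), lambda = lambda,
                 nthread = 1L, seed = as.integer(seed))
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = nrounds, verbose = 0)
}

xgbScore <- function(model, x) {
  as.numeric(stats::predict(model, xgboost::xgb.DMatrix(data = x)))
}

# stratified (optionally participant-grouped) inner folds over row indices
innerFoldIds <- function(labels, k, groups = NULL) {
  if (is.null(groups)) groups <- paste0("row", seq_along(labels))
  gLab <- tapply(as.character(labels), groups, function(v) v[1])
  fold <- integer(0)
  for (lab in sort(unique(gLab))) {
    ids <- sample(names(gLab)[gLab == lab])
    fold <- c(fold, stats::setNames(rep_len(seq_len(k), length(ids)), ids))
  }
  unname(fold[groups])
}

#' Fit the embedding classifier with grid search
#'
#' Gradient-boosted decision trees (regularized additive-tree objective:
#' per-example loss plus per-tree complexity penalty) on embedding rows.
#' The grid over learning rate, tree depth and L2 regularization is scored
#' by inner cross-validated AUC on the training data only; the winner is
#' refit on the full training split.
#'
#' @param x numeric matrix, one row per training example.
#' @param labels class labels (`control` / `impaired`).
#' @param grid from [classifierGrid()].
#' @param seed integer seed (inner fold shuffling and fits).
#' @param groups optional grouping vector (participant ids) so inner folds
#'   are leakage-safe too.
#' @return list `model`, `best` (chosen row of the grid), `innerAuc`.
#' @export
fitEmbeddingClassifier <- function(x, labels, grid = classifierGrid(),
                                   seed = 1L, groups = NULL) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("training data contains a single class")
  y01 <- as.integer(labels == "impaired")
  x <- as.matrix(x)
  innerK <- attr(grid, "innerK")
  nrounds <- attr(grid, "nrounds")
  foldId <- withSeed(seed, innerFoldIds(labels, innerK, groups))
  innerAuc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    aucs <- numeric(0)
    for (f in seq_len(innerK)) {
      tr <- foldId != f
      if (length(unique(labels[!tr])) < 2L || length(unique(labels[tr])) < 2L)
        next
      fit <- xgbFit(x[tr, , drop = FALSE], y01[tr], grid$eta[gi],
                    grid$maxDepth[gi], grid$lambda[gi], nrounds, seed)
      aucs <- c(aucs, aucRank(xgbScore(fit, x[!tr, , drop = FALSE]),
                              labels[!tr]))
    }
    innerAuc[gi] <- if (length(aucs)) mean(aucs) else NA_real_
  }
  best <- which.max(innerAuc)
  model <- xgbFit(x, y01, grid$eta[best], grid$maxDepth[best],
                  grid$lambda[best], nrounds, seed)
  list(model = model, best = grid[best, , drop = FALSE],
       innerAuc = innerAuc[best])
}

# participant-grouped 80/20 split of one training fold for encoder
# validation; returns transcript-level masks or NULL when the fold is too
# small to hold out 2+ images per class
splitEncoderVal <- function(labels, participants, valFraction, seed) {
  if (valFraction <= 0) return(NULL)
  partLabel <- vapply(split(labels, participants), function(v) v[1],
                      character(1))
  valParts <- withSeed(seed, {
    out <- character(0)
    for (lab in sort(unique(partLabel))) {
      ids <- names(partLabel)[partLabel == lab]
      nVal <- max(1L, round(valFraction * length(ids)))
      out <- c(out, sample(ids, nVal))
    }
    out
  })
  val <- participants %in% valParts
  ok <- function(mask) all(table(factor(labels[mask],
                                        levels = unique(labels))) >= 2)
  if (!ok(val) || !ok(!val)) return(NULL)
  list(fit = !val, val = val)
}

# balanced pairs restricted to a transcript subset, indices remapped to
# the full image list
pairsWithin <- function(mask, labels, nPairs, seed) {
  idx <- which(mask)
  p <- generatePairs(labels[idx], nPairs, seed)
  p$i <- idx[p$i]
  p$j <- idx[p$j]
  p
}

# corpus -> list of RecurrenceImages (deterministic, no training involved)
corpusImages <- function(corpus, targetLength = 512L,
                         mode = c("exact", "heaviside"), imageSize = 128L,
                         interp = "area") {
  mode <- match.arg(mode)
  rec <- corpusRecords(corpus)
  lapply(seq_len(nrow(rec)), function(i) {
    s <- standardizeLength(
      encodeText(rec$text[i], transcriptId = rec$transcript_id[i]),
      targetLength)
    asRecurrenceImage(recurrenceMatrix(s, mode), imageSize, interp)
  })
}

#' Shuffle corpus labels at the participant level
#'
#' Permutation-null helper: participant-to-label assignment is permuted
#' (class counts preserved), and every transcript inherits its
#' participant's permuted label. Permuting at the transcript level would
#' split a participant across classes and break grouped stratification.
#'
#' @param corpus a [TranscriptCorpus-class].
#' @param seed integer seed.
#' @return a [TranscriptCorpus-class] with permuted labels.
#' @export
permuteCorpusLabels <- function(corpus, seed = 1L) {
  rec <- corpusRecords(corpus)
  partLabel <- vapply(split(rec$label, rec$participant_id),
                      function(v) v[1], character(1))
  perm <- withSeed(seed,
                   stats::setNames(sample(unname(partLabel)),
                                   names(partLabel)))
  rec$label <- unname(perm[rec$participant_id])
  new("TranscriptCorpus", records = rec)
}

#' Grouped cross-validation of embedding discriminability
#'
#' The full pipeline under leakage-safe, participant-grouped stratified
#' k-fold cross-validation: per fold, the Siamese encoder is trained only
#' on training-fold recurrence images, training-fold embeddings fit the
#' gradient-boosted classifier (grid search by inner CV AUC), and the
#' held-out fold is embedded and scored. Fold AUCs are summarized with a
#' bootstrap confidence interval for the mean.
#'
#' The per-fold encoder retraining is the default, leakage-safe protocol;
#' `encoderScope = "single"` reproduces the optimistic variant in which one
#' encoder is trained on all images before cross-validation.
#'
#' @param corpus a [TranscriptCorpus-class].
#' @param k outer folds (default 5).
#' @param seed master seed; fans out deterministically to fold assignment,
#'   encoder initialization, pair sampling and the classifier.
#' @param targetLength standardized sequence length (default 512).
#' @param mode recurrence mode, `"exact"` (default) or `"heaviside"`.
#' @param imageSize recurrence-image side (default 128).
#' @param interp image resampling kernel (default `"area"`).
#' @param config training configuration from [trainConfig()].
#' @param grid classifier grid from [classifierGrid()].
#' @param pairsPerFold pairs drawn per training fold; default
#'   `config$pairsPerImage` times the training-fold image count, rounded
#'   even.
#' @param B bootstrap resamples for the CI.
#' @param encoderScope `"per_fold"` (default) or `"single"`.
#' @return a [CVReport-class]; per-fold predictions are attached as
#'   attribute `"predictions"`.
#' @export
evaluateCV <- function(corpus, k = 5L, seed = 1L, targetLength = 512L,
                       mode = "exact", imageSize = 128L, interp = "area",
                       config = trainConfig(), grid = classifierGrid(),
                       pairsPerFold = NULL, B = 10000L,
                       encoderScope = c("per_fold", "single")) {
  encoderScope <- match.arg(encoderScope)
  rec <- corpusRecords(corpus)
  images <- corpusImages(corpus, targetLength, mode, imageSize, interp)
  folds <- participantFolds(corpus, k, seed)
  foldOf <- transcriptFolds(folds, corpus)
  singleEnc <- NULL
  if (encoderScope == "single") {
    nP <- pairsPerFold
    if (is.null(nP)) nP <- 2L * ((config$pairsPerImage * nrow(rec)) %/% 2L)
    prs <- generatePairs(rec$label, nP, seed = seed)
    cfg <- config; cfg$seed <- seed
    singleEnc <- trainSiamese(buildEncoder(seed), images, prs, cfg)
  }
  foldAucs <- numeric(k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- foldOf != f
    trainParts <- unique(rec$participant_id[tr])
    testParts <- unique(rec$participant_id[!tr])
    stopifnot(length(intersect(trainParts, testParts)) == 0L)
    foldSeed <- seed * 13L + f
    enc <- if (is.null(singleEnc)) {
      nP <- pairsPerFold
      if (is.null(nP)) nP <- 2L * ((config$pairsPerImage * sum(tr)) %/% 2L)
      cfg <- config; cfg$seed <- foldSeed
      # encoder validation split (grouped 80/20 within the training fold):
      # early stopping on held-out pair loss limits memorization of the
      # training images
      sp <- splitEncoderVal(rec$label[tr], rec$participant_id[tr],
                            config$valFraction %||% 0.2, foldSeed + 1L)
      fitted <- tryCatch({
        if (is.null(sp)) {
          prs <- generatePairs(rec$label[tr], nP, seed = foldSeed)
          trainSiamese(buildEncoder(foldSeed), images[tr], prs, cfg)
        } else {
          prs <- pairsWithin(sp$fit, rec$label[tr], nP, foldSeed)
          nVal <- 2L * max(10L, nP %/% 8L)
          vprs <- pairsWithin(sp$val, rec$label[tr], nVal, foldSeed + 2L)
          trainSiamese(buildEncoder(foldSeed), images[tr], prs, cfg,
                       valPairs = vprs)
        }
      }, error = function(e) stop("fold ", f, ": ", conditionMessage(e)))
      fitted
    } else singleEnc
    embTrain <- embedImages(enc, images[tr])
    embTest <- embedImages(enc, images[!tr])
    clf <- tryCatch(
      fitEmbeddingClassifier(embTrain, rec$label[tr], grid, seed = foldSeed,
                             groups = rec$participant_id[tr]),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e)))
    scores <- xgbScore(clf$model, embTest)
    foldAucs[f] <- aucRank(scores, rec$label[!tr])
    preds[[f]] <- data.frame(transcript_id = rec$transcript_id[!tr],
                             score = scores, label = rec$label[!tr],
                             fold = f)
  }
  report <- makeCVReport(foldAucs, B = B, seed = seed, config = list(
    representation = "char_recurrence_siamese",
    k = k, seed = seed, targetLength = targetLength, mode = mode,
    imageSize = imageSize, interp = interp,
    margin = config$margin, learningRate = config$learningRate,
    epochs = config$epochs, batchSize = config$batchSize,
    pairsPerFold = pairsPerFold, encoderScope = encoderScope))
  attr(report, "predictions") <- do.call(rbind, preds)
  report
}

#' Write a CV report to JSON (and optionally per-fold predictions to CSV)
#'
#' @param report a [CVReport-class].
#' @param path output JSON path.
#' @param predictionsPath optional CSV path for per-fold predictions.
#' @return `path`, invisibly.
#' @export
writeCVReport <- function(report, path, predictionsPath = NULL) {
  out <- list(fold_aucs = report@foldAucs, mean = report@mean,
              std = report@std, min = report@min, max = report@max,
              ci_low = report@ciLow, ci_high = report@ciHigh,
              config = report@config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  pr <- attr(report, "predictions")
  if (!is.null(predictionsPath) && !is.null(pr))
    utils::write.csv(pr, predictionsPath, row.names = FALSE)
  invisible(path)
}
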
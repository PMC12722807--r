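test_that("participant folds group transcripts and stratify classes", {
  corp <- corpusFromTexts(
    texts = rep("a boy on a stool .", 13),
    labels = c(rep("control", 6), rep("impaired", 7)),
    participant_id = c("a", "a", "b", "c", "d", "e",
                       "f", "f", "f", "g", "h", "i", "j"),
    transcript_id = paste0("t", 1:13))
  f <- participantFolds(corp, k = 5, seed = 3)
  expect_s4_class(f, "FoldAssignment")
  # all transcripts of one participant land in one fold
  tf <- transcriptFolds(f, corp)
  expect_equal(length(unique(tf[1:2])), 1L)   # participant a
  expect_equal(length(unique(tf[7:9])), 1L)   # participant f
  # each fold holds one control participant (5 controls, k = 5)
  rec <- corpusRecords(corp)
  perFold <- table(f@fold[unique(rec$participant_id[rec$label == "control"])])
  expect_true(all(perFold == 1))
  expect_error(participantFolds(corp, k = 6), "at least k")
})

test_that("summarize reproduces the printed fold statistics", {
  s <- summarizeFolds(c(0.949, 0.951, 0.943, 0.982, 0.944))
  expect_equal(round(s$mean, 3), 0.954)
  expect_equal(s$mean, 0.9538)
  expect_equal(s$min, 0.943)
  expect_equal(s$max, 0.982)
  expect_equal(s$std, sd(c(0.949, 0.951, 0.943, 0.982, 0.944)))
  expect_warning(one <- summarizeFolds(0.5), "single fold")
  expect_equal(one$std, 0)
  expect_equal(summarizeFolds(c(0.9, 0.9, 0.9))$std, 0)
  expect_error(summarizeFolds(numeric(0)), "empty")
})

test_that("bootstrap CI is a percentile bootstrap of the mean", {
  aucs <- c(0.949, 0.951, 0.943, 0.982, 0.944)
  ci <- bootstrapCI(aucs, B = 10000, seed = 1)
  expect_identical(ci, bootstrapCI(aucs, B = 10000, seed = 1))
  expect_equal(bootstrapCI(rep(0.9, 5), B = 200, seed = 1),
               c(ciLow = 0.9, ciHigh = 0.9))
  # bootstrap-of-means is bracketed by the sample extremes and mean
  expect_true(min(aucs) <= ci[1] && ci[1] <= mean(aucs))
  expect_true(mean(aucs) <= ci[2] && ci[2] <= max(aucs))
  expect_error(bootstrapCI(0.9), "at least 2")
  expect_error(bootstrapCI(aucs, B = 10), "at least 100")
})

test_that("rank AUC handles ties and matches an independent implementation", {
  sc <- c(0.9, 0.8, 0.8, 0.3, 0.2)
  lab <- c("impaired", "impaired", "control", "control", "impaired")
  expect_equal(aucRank(sc, lab), {
    pos <- sc[lab == "impaired"]; neg <- sc[lab != "impaired"]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  })
  expect_equal(aucRank(c(3, 2, 1), c(1, 0, 0)), 1)
  skip_if_not_installed("pROC")
  set.seed(6)
  s <- rnorm(60); l <- rbinom(60, 1, 0.5)
  expect_equal(aucRank(s, l),
               as.numeric(suppressMessages(pROC::auc(l, s,
                                                     direction = "<"))))
})

test_that("classifier grid search selects by inner CV and refits", {
  set.seed(5)
  # linearly separable toy embeddings
  x <- rbind(matrix(rnorm(20, 3), 10), matrix(rnorm(20, -3), 10))
  y <- rep(c("impaired", "control"), each = 10)
  fit <- fitEmbeddingClassifier(x, y, classifierGrid(eta = 0.3,
                                                     maxDepth = 3,
                                                     lambda = 1), seed = 5)
  expect_equal(nrow(fit$best), 1L)
  expect_equal(aucRank(charRQA:::xgbScore(fit$model, x), y), 1)
  expect_error(fitEmbeddingClassifier(x, rep("impaired", 20)),
               "single class")
})

test_that("shuffled labels keep inner-CV AUC near chance", {
  set.seed(11)
  x <- matrix(rnorm(200 * 16), 200)
  y <- sample(rep(c("control", "impaired"), each = 100))
  fit <- fitEmbeddingClassifier(x, y, seed = 11)
  expect_gte(fit$innerAuc, 0.35)
  expect_lte(fit$innerAuc, 0.65)
})

test_that("label permutation preserves class counts at participant level", {
  corp <- loadCorpusDir(tinyCorpusDir(n = 6, participants = 4, seed = 7))
  perm <- permuteCorpusLabels(corp, seed = 3)
  expect_equal(classCounts(perm), classCounts(corp))
  rec <- corpusRecords(perm)
  expect_true(all(tapply(rec$label, rec$participant_id,
                         function(v) length(unique(v))) == 1))
})

test_that("evaluateCV runs the leakage-safe pipeline end to end (small)", {
  corp <- loadCorpusDir(tinyCorpusDir(n = 8, participants = 4, seed = 13))
  rep <- evaluateCV(corp, k = 2, seed = 4, targetLength = 256,
                    config = trainConfig(epochs = 2, seed = 4),
                    grid = classifierGrid(eta = 0.3, maxDepth = 3,
                                          lambda = 1),
                    pairsPerFold = 24, B = 500)
  expect_s4_class(rep, "CVReport")
  expect_length(foldAucs(rep), 2)
  expect_true(all(foldAucs(rep) >= 0 & foldAucs(rep) <= 1))
  expect_true(rep@min <= rep@mean && rep@mean <= rep@max)
  preds <- attr(rep, "predictions")
  expect_equal(sort(preds$transcript_id),
               sort(corpusRecords(corp)$transcript_id))
  # single-encoder variant shares one encoder across folds
  rep2 <- evaluateCV(corp, k = 2, seed = 4, targetLength = 256,
                     config = trainConfig(epochs = 1, seed = 4),
                     grid = classifierGrid(eta = 0.3, maxDepth = 3,
                                           lambda = 1),
                     pairsPerFold = 24, B = 500,
                     encoderScope = "single")
  expect_s4_class(rep2, "CVReport")
  expect_error(evaluateCV(corp, k = 20, seed = 1), "at least k")
})

test_that("CV reports serialize to JSON with predictions", {
  r <- charRQA:::makeCVReport(c(0.8, 0.85, 0.9), B = 500, seed = 2,
                              config = list(representation = "test"))
  f <- tempfile(fileext = ".json")
  writeCVReport(r, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$fold_aucs, c(0.8, 0.85, 0.9))
  expect_equal(back$mean, 0.85)
})
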
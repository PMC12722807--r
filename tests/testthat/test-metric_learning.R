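test_that("contrastive loss matches its closed forms", {
  expect_equal(contrastiveLoss(0, 0, 1), 0)
  expect_equal(contrastiveLoss(1.5, 1, 1), 0)
  expect_equal(contrastiveLoss(0, 1, 1), 0.5)
  expect_equal(contrastiveLoss(2, 0, 1), 2)
  # randomized identity against direct evaluation of the formula
  set.seed(4)
  d <- runif(50, 0, 3); y <- rbinom(50, 1, 0.5); m <- runif(50, 0.5, 2)
  expect_equal(contrastiveLoss(d, y, m),
               (1 - y) * 0.5 * d^2 + y * 0.5 * pmax(0, m - d)^2)
  expect_error(contrastiveLoss(-1, 0), "non-negative")
  expect_error(contrastiveLoss(1, 0, m = 0), "positive")
})

test_that("loss gradient in the distance matches finite differences", {
  h <- 1e-6
  for (d in c(0.2, 0.7, 1.4)) {
    for (y in 0:1) {
      fd <- (contrastiveLoss(d + h, y) - contrastiveLoss(d - h, y)) / (2 * h)
      an <- if (y == 0) d else if (d < 1) -(1 - d) else 0
      expect_equal(fd, an, tolerance = 1e-5)
    }
  }
})

test_that("generatePairs balances classes without self-pairs", {
  labels <- rep(c("control", "impaired"), each = 10)
  p <- generatePairs(labels, 100, seed = 2)
  expect_equal(sum(p$y == 0), 50)
  expect_equal(sum(p$y == 1), 50)
  expect_true(all(p$i != p$j))
  same <- p[p$y == 0, ]
  expect_true(all(labels[same$i] == labels[same$j]))
  diff <- p[p$y == 1, ]
  expect_true(all(labels[diff$i] != labels[diff$j]))
  expect_identical(generatePairs(labels, 100, seed = 2), p)
  expect_error(generatePairs(c("control", rep("impaired", 5)), 10),
               "at least 2")
})

test_that("encoder architecture is fixed and reproducibly initialized", {
  expect_error(buildEncoder(inputSize = 64), "fixed")
  e1 <- buildEncoder(seed = 5)
  e2 <- buildEncoder(seed = 5)
  expect_identical(e1@weights, e2@weights)
  img <- matrix(runif(128 * 128), 128, 128)
  emb1 <- embedImages(e1, list(img))
  emb2 <- embedImages(e2, list(img))
  expect_equal(dim(emb1), c(1L, 128L))
  expect_identical(emb1, emb2)
  expect_error(embedImages(e1, list(matrix(0, 64, 64))), "size")
})

test_that("backpropagated gradients match finite differences", {
  set.seed(8)
  A <- matrix(runif(128 * 128), 128, 128)
  B <- matrix(runif(128 * 128), 128, 128)
  w <- buildEncoder(seed = 8)@weights
  for (y in c(0L, 1L)) {
    res <- charRQA:::siamese_pair_grad_cpp(A, B, w, 1.0, y)
    # dense-layer entries are smooth in the weights; check the largest
    for (nm in c("W3", "b3")) {
      ii <- order(abs(res$grads[[nm]]), decreasing = TRUE)[1:2]
      for (i in ii) {
        h <- 3e-3
        wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
        wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
        fd <- (charRQA:::siamese_pair_loss_cpp(A, B, wp, 1, y) -
               charRQA:::siamese_pair_loss_cpp(A, B, wm, 1, y)) / (2 * h)
        expect_equal(res$grads[[nm]][i], fd, tolerance = 0.02)
      }
    }
    # conv entries cross max-pool switches; allow a looser band
    i <- which.max(abs(res$grads$W2))
    h <- 3e-3
    wp <- w; wp$W2[i] <- wp$W2[i] + h
    wm <- w; wm$W2[i] <- wm$W2[i] - h
    fd <- (charRQA:::siamese_pair_loss_cpp(A, B, wp, 1, y) -
           charRQA:::siamese_pair_loss_cpp(A, B, wm, 1, y)) / (2 * h)
    expect_equal(res$grads$W2[i], fd, tolerance = 0.1)
  }
})

test_that("shared weights embed an image identically in either branch", {
  # a single parameter set serves both branches, so swapping the pair
  # order must swap-but-not-change the embeddings (distance unchanged)
  set.seed(9)
  A <- matrix(runif(128 * 128), 128, 128)
  B <- matrix(runif(128 * 128), 128, 128)
  w <- buildEncoder(seed = 9)@weights
  l1 <- charRQA:::siamese_pair_loss_cpp(A, B, w, 1.0, 1L)
  l2 <- charRQA:::siamese_pair_loss_cpp(B, A, w, 1.0, 1L)
  expect_equal(l1, l2, tolerance = 1e-6)
  e <- embedImages(buildEncoder(seed = 9), list(A, A))
  expect_identical(e[1, ], e[2, ])
})

test_that("training on separable patterns reduces loss and organizes space", {
  pats <- patternImages(10, noise = 0.05, seed = 3)
  pairs <- generatePairs(pats$labels, 200, seed = 3)
  enc <- buildEncoder(seed = 3)
  fit <- trainSiamese(enc, pats$images, pairs,
                      trainConfig(epochs = 10, seed = 3))
  hist <- lossHistory(fit)
  expect_gte(hist$loss[1], utils::tail(hist$loss, 1))
  expect_equal(fit@config$margin, 1.0)
  expect_equal(fit@config$learningRate, 0.001)

  held <- patternImages(6, noise = 0.05, seed = 41)
  emb <- embedImages(fit, held$images)
  D <- as.matrix(dist(emb))
  same <- (outer(held$labels, held$labels, "==") & upper.tri(D))
  diffm <- (!outer(held$labels, held$labels, "==")) & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diffm]))
  # dissimilar pairs should straddle the margin in the median
  expect_gte(median(D[diffm]), 0.9)

  expect_error(trainSiamese(enc, pats$images, pairs[0, ]), "empty")
})

test_that("training is reproducible under one master seed", {
  pats <- patternImages(4, seed = 12)
  pairs <- generatePairs(pats$labels, 16, seed = 12)
  f1 <- trainSiamese(buildEncoder(12), pats$images, pairs,
                     trainConfig(epochs = 2, seed = 12))
  f2 <- trainSiamese(buildEncoder(12), pats$images, pairs,
                     trainConfig(epochs = 2, seed = 12))
  expect_identical(lossHistory(f1), lossHistory(f2))
  expect_identical(f1@weights, f2@weights)
})
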
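#' Contrastive loss
#'
#' For a pair at embedding distance `d` with label `y` (0 = same class,
#' 1 = different class) and margin `m`:
#' `L = (1 - y) * d^2 / 2 + y * max(0, m - d)^2 / 2`.
#' Same-class pairs are pulled together by the squared distance; different-
#' class pairs are pushed apart until they clear the margin.
#'
#' @param d non-negative Euclidean distance(s) between embeddings.
#' @param y pair label(s), 0 (same class) or 1 (different class).
#' @param m positive margin (default 1).
#' @return loss value(s), vectorized over the inputs.
#' @examples
#' contrastiveLoss(0, 1)    # 0.5  (identical embeddings, different class)
#' contrastiveLoss(2, 0)    # 2    (distant embeddings, same class)
#' @export
contrastiveLoss <- function(d, y, m = 1) {
  if (any(d < 0)) stop("distance must be non-negative")
  if (any(m <= 0)) stop("margin must be positive")
  if (!all(y %in% c(0, 1))) stop("pair label must be 0 or 1")
  (1 - y) * 0.5 * d^2 + y * 0.5 * pmax(0, m - d)^2
}

#' Training configuration for the Siamese encoder
#'
#' Margin and learning rate default to the method's stated values
#' (m = 1.0, Adam with learning rate 0.001). Batch size, epochs and the
#' pair budget are artifact defaults, surfaced here and echoed into the
#' training history.
#'
#' @param margin contrastive margin (default 1.0).
#' @param learningRate Adam learning rate (default 0.001).
#' @param batchSize minibatch size in pairs (default 32).
#' @param epochs maximum training epochs (default 20).
#' @param pairsPerImage sampled pairs are `pairsPerImage * n_images`,
#'   rounded to an even count (default 4).
#' @param earlyStopTol minimum epoch-loss improvement counted as progress
#'   (default 1e-4).
#' @param earlyStopPatience epochs without progress before stopping
#'   (default 5).
#' @param valFraction fraction of training-fold participants held out as
#'   an encoder validation split (default 0.2); early stopping then
#'   monitors held-out pair loss and the best-epoch weights are restored,
#'   which keeps the encoder from memorizing the training images. Set to 0
#'   to monitor training loss instead.
#' @param seed master seed fanned out to parameter initialization, pair
#'   sampling and batch shuffling.
#' @return a named list.
#' @export
trainConfig <- function(margin = 1.0, learningRate = 0.001, batchSize = 32L,
                        epochs = 20L, pairsPerImage = 4L,
                        earlyStopTol = 1e-4, earlyStopPatience = 5L,
                        valFraction = 0.2, seed = 1L) {
  stopifnot(margin > 0, learningRate > 0, batchSize >= 1, epochs >= 1,
            valFraction >= 0, valFraction < 1)
  list(margin = margin, learningRate = learningRate,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       pairsPerImage = as.integer(pairsPerImage),
       earlyStopTol = earlyStopTol,
       earlyStopPatience = as.integer(earlyStopPatience),
       valFraction = valFraction,
       seed = as.integer(seed))
}

#' Build the twin-branch encoder
#'
#' Instantiates the fixed architecture (128x128x1 input; Conv 32@3x3 ReLU;
#' MaxPool 2x2; Conv 64@3x3 ReLU; MaxPool 2x2; Flatten; Dense 128 ReLU)
#' with Glorot-uniform weights. The architecture is part of the method:
#' requesting any other layout is an error.
#'
#' @param seed integer seed for weight initialization.
#' @param inputSize input side length; must be 128.
#' @param embedDim embedding dimension; must be 128.
#' @return an untrained [SiameseEncoder-class].
#' @export
buildEncoder <- function(seed = 1L, inputSize = 128L, embedDim = 128L) {
  if (inputSize != 128L || embedDim != 128L)
    stop("the encoder architecture is fixed: 128x128 input, ",
         "128-dimensional embedding")
  d <- encoderDims(inputSize)
  glorot <- function(nr, nc, fanIn, fanOut) {
    lim <- sqrt(6 / (fanIn + fanOut))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  weights <- withSeed(seed, list(
    W1 = glorot(9, 32, 9, 9 * 32),
    b1 = numeric(32),
    W2 = glorot(288, 64, 288, 9 * 64),
    b2 = numeric(64),
    W3 = glorot(d$flat, embedDim, d$flat, embedDim),
    b3 = numeric(embedDim)
  ))
  new("SiameseEncoder", weights = weights, inputSize = as.integer(inputSize),
      embedDim = as.integer(embedDim), trained = FALSE,
      history = data.frame(epoch = integer(), loss = numeric()),
      config = list(initSeed = as.integer(seed)))
}

encoderDims <- function(side) {
  c1 <- side - 2L; p1 <- c1 %/% 2L; c2 <- p1 - 2L; p2 <- c2 %/% 2L
  list(c1 = c1, p1 = p1, c2 = c2, p2 = p2, flat = p2 * p2 * 64L)
}

#' Sample balanced training pairs
#'
#' Draws `nPairs/2` same-class and `nPairs/2` different-class pairs of
#' image indices, without replacement where the class sizes allow it, never
#' pairing an image with itself. Reproducible under `seed`.
#'
#' @param labels character or factor vector of image class labels (two
#'   classes, each with at least 2 members).
#' @param nPairs even number of pairs to draw.
#' @param seed integer seed.
#' @return data.frame with columns `i`, `j` (indices into `labels`) and `y`
#'   (0 same class, 1 different class).
#' @export
generatePairs <- function(labels, nPairs, seed = 1L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("exactly two classes required")
  idx <- split(seq_along(labels), labels)
  if (any(vapply(idx, length, integer(1)) < 2L))
    stop("each class needs at least 2 images for same-class pairs")
  if (nPairs < 2L || nPairs %% 2L != 0L)
    stop("nPairs must be an even number >= 2")
  half <- nPairs %/% 2L
  samePool <- do.call(rbind, lapply(idx, function(v) {
    cmb <- utils::combn(v, 2L)
    cbind(cmb[1, ], cmb[2, ])
  }))
  diffPool <- as.matrix(expand.grid(idx[[1]], idx[[2]]))
  pick <- function(pool, n) {
    if (n <= nrow(pool)) pool[sample.int(nrow(pool), n), , drop = FALSE]
    else pool[sample.int(nrow(pool), n, replace = TRUE), , drop = FALSE]
  }
  sampled <- withSeed(seed, list(same = pick(samePool, half),
                                 diff = pick(diffPool, half)))
  same <- sampled$same
  diff <- sampled$diff
  out <- data.frame(i = c(same[, 1], diff[, 1]),
                    j = c(same[, 2], diff[, 2]),
                    y = rep(c(0L, 1L), each = half))
  rownames(out) <- NULL
  out
}

# stack RecurrenceImages (or numeric matrices) into a pixels x n matrix
imageStack <- function(images) {
  cols <- lapply(images, function(im) {
    p <- if (is(im, "RecurrenceImage")) recurrenceValues(im) else im
    as.numeric(p)
  })
  do.call(cbind, cols)
}

#' Train the Siamese encoder by contrastive loss
#'
#' Minibatch gradient descent (Adam) on the mean contrastive loss over
#' labeled image pairs; both branches share one parameter set by
#' construction. Per-epoch mean training loss is recorded in the history,
#' along with the configuration (margin, learning rate, seed). Training
#' stops early when the epoch loss stops improving (see [trainConfig()]).
#'
#' @param encoder a [SiameseEncoder-class] from [buildEncoder()].
#' @param images list of [RecurrenceImage-class] (or 128x128 matrices).
#' @param pairs data.frame from [generatePairs()] (columns `i`, `j`, `y`).
#' @param config list from [trainConfig()].
#' @param valPairs optional data.frame of held-out pairs (same columns,
#'   indices into `images`); when supplied, early stopping monitors the
#'   mean contrastive loss on these pairs and the best-epoch weights are
#'   restored.
#' @return the trained [SiameseEncoder-class] with loss history.
#' @export
trainSiamese <- function(encoder, images, pairs, config = trainConfig(),
                         valPairs = NULL) {
  stopifnot(is(encoder, "SiameseEncoder"))
  if (nrow(pairs) == 0L) stop("empty pair list")
  X <- imageStack(images)
  if (nrow(X) != encoder@inputSize^2)
    stop("image size does not match the encoder input")
  # batch-shuffle stream, offset so it is distinct from the init stream
  order <- withSeed(config$seed + 1L,
                    vapply(seq_len(config$epochs),
                           function(e) sample.int(nrow(pairs)),
                           integer(nrow(pairs))))
  if (is.null(valPairs))
    valPairs <- data.frame(i = integer(0), j = integer(0), y = integer(0))
  fit <- siamese_train_cpp(X, as.integer(pairs$i), as.integer(pairs$j),
                           as.integer(pairs$y), encoder@weights,
                           config$margin, config$learningRate,
                           config$batchSize,
                           matrix(as.integer(order), nrow = nrow(pairs)),
                           config$earlyStopTol, config$earlyStopPatience,
                           as.integer(valPairs$i), as.integer(valPairs$j),
                           as.integer(valPairs$y))
  encoder@weights <- fit$weights
  encoder@trained <- TRUE
  encoder@history <- data.frame(epoch = seq_along(fit$loss),
                                loss = fit$loss,
                                val_loss = if (length(fit$val_loss))
                                  fit$val_loss else NA_real_)
  encoder@config <- utils::modifyList(encoder@config, config)
  encoder@config$bestEpoch <- fit$best_epoch
  encoder
}

#' Embed recurrence images
#'
#' Maps each image through the (shared-weight) encoder to its
#' 128-dimensional embedding; deterministic for a fixed encoder, order
#' preserved.
#'
#' @param encoder a [SiameseEncoder-class].
#' @param images list of [RecurrenceImage-class] (or matrices).
#' @return numeric matrix, one row per image, 128 columns.
#' @export
embedImages <- function(encoder, images) {
  stopifnot(is(encoder, "SiameseEncoder"))
  X <- imageStack(images)
  if (nrow(X) != encoder@inputSize^2)
    stop("image size does not match the encoder input")
  t(siamese_embed_cpp(X, encoder@weights))
}
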
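seqOf <- function(codes, pad = 0L) {
  codes <- as.integer(codes)
  eff <- length(codes)
  if (pad > 0) codes <- c(codes, integer(pad))
  new("SymbolSequence", codes = codes, effectiveLength = eff,
      transcriptId = "test")
}

test_that("epsilon is 0.1 times the population standard deviation", {
  expect_equal(epsilonThreshold(seqOf(c(1, 2, 3))), 0.1 * sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(epsilonThreshold(seqOf(c(5, 5, 5, 5))), 0)
  expect_equal(epsilonThreshold(seqOf(c(1, 1, 27, 27))), 1.3)
  # padding must not shift the threshold
  expect_equal(epsilonThreshold(seqOf(c(1, 2, 3), pad = 20)),
               epsilonThreshold(seqOf(c(1, 2, 3))))
  expect_error(epsilonThreshold(seqOf(5)), "degenerate")
})

test_that("exact mode marks symbolic equivalence", {
  rp <- recurrenceMatrix(encodeText("see"), mode = "exact")
  expect_equal(recurrenceValues(rp),
               matrix(c(1, 0, 0, 0, 1, 1, 0, 1, 1), 3, byrow = TRUE))
  allsame <- recurrenceMatrix(seqOf(c(7, 7, 7, 7)))
  expect_equal(recurrenceValues(allsame), matrix(1, 4, 4))
})

test_that("heaviside mode with eps below 1 equals exact mode", {
  s <- seqOf(c(1, 2, 3))
  expect_identical(recurrenceValues(recurrenceMatrix(s, "heaviside")),
                   diag(3))
  expect_identical(recurrenceValues(recurrenceMatrix(s, "heaviside")),
                   recurrenceValues(recurrenceMatrix(s, "exact")))
  # a squashed-range sequence pushes eps above 1 and triggers the warning
  wide <- seqOf(rep(c(1, 27), each = 10))
  expect_warning(recurrenceMatrix(wide, "heaviside"), ">= 1")
})

test_that("both modes agree with the brute-force double-loop oracle", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(2:50, 1)
    codes <- sample(1:28, n, replace = TRUE)
    s <- seqOf(codes)
    expect_equal(recurrenceValues(recurrenceMatrix(s, "exact")),
                 bruteRecurrence(codes))
    eps <- epsilonThreshold(s)
    M <- suppressWarnings(recurrenceMatrix(s, "heaviside"))
    expect_equal(recurrenceValues(M), bruteRecurrence(codes, eps))
  }
})

test_that("pad region is masked and structure is symmetric and reflexive", {
  s <- standardizeLength(encodeText("see a boy"), 16)
  rp <- recurrenceMatrix(s)
  M <- recurrenceValues(rp)
  expect_true(isSymmetric(M))
  expect_equal(diag(M)[1:9], rep(1, 9))
  expect_equal(M[10:16, ], matrix(0, 7, 16))
  expect_equal(M[, 10:16], matrix(0, 16, 7))
  expect_true(validObject(rp))
})

test_that("shuffling preserves exact-mode recurrence rate but not the matrix", {
  set.seed(23)
  codes <- sample(1:6, 30, replace = TRUE)
  s1 <- seqOf(codes)
  s2 <- seqOf(sample(codes))
  r1 <- recurrenceMatrix(s1)
  r2 <- recurrenceMatrix(s2)
  expect_false(identical(recurrenceValues(r1), recurrenceValues(r2)))
  expect_equal(rqaMetrics(r1)$recurrence_rate,
               rqaMetrics(r2)$recurrence_rate)
})

test_that("images are resized into [0,1] with the chosen kernel", {
  rp <- recurrenceMatrix(standardizeLength(encodeText("the boy and the girl"),
                                           256))
  img <- asRecurrenceImage(rp)
  px <- recurrenceValues(img)
  expect_equal(dim(px), c(128L, 128L))
  expect_gte(min(px), 0)
  expect_lte(max(px), 1)

  # identity resize under nearest
  small <- recurrenceMatrix(seqOf(rep(1:4, 32)))  # 128 long
  expect_equal(recurrenceValues(asRecurrenceImage(small, 128, "nearest")),
               recurrenceValues(small))
  # constant image invariant under any kernel
  ones <- recurrenceMatrix(seqOf(rep(7, 256)))
  for (k in c("area", "bilinear", "nearest"))
    expect_equal(recurrenceValues(asRecurrenceImage(ones, 128, k)),
                 matrix(1, 128, 128))
  # 4x4 checkerboard area-averaged to 2x2 is uniformly 0.5
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  W <- charRQA:::resampleWeights(4, 2, "area")
  expect_equal(W %*% cb %*% t(W), matrix(0.5, 2, 2))
  # all-zero matrix maps to all-zero image (pad-only corner case)
  z <- new("RecurrencePlot",
           matrix = rbind(cbind(diag(2), matrix(0, 2, 2)), matrix(0, 2, 4)),
           effectiveLength = 2L, epsilon = 0, mode = "exact",
           transcriptId = "z")
  expect_true(all(recurrenceValues(asRecurrenceImage(z, 4, "area")) >= 0))
  expect_error(asRecurrenceImage(z, 1), "at least 2")
})

test_that("RQA metrics match hand-enumerated diagonals", {
  id3 <- recurrenceMatrix(seqOf(c(1, 2, 3)))
  m <- rqaMetrics(id3)
  expect_equal(m$recurrence_rate, 1 / 3)
  expect_equal(m$determinism, 0)
  expect_equal(m$longest_diagonal, 0L)

  allsame <- recurrenceMatrix(seqOf(c(7, 7, 7, 7)))
  m <- rqaMetrics(allsame)
  expect_equal(m$recurrence_rate, 1)
  expect_equal(m$longest_diagonal, 3L)
  # the two corner points sit on length-1 diagonals, so 10 of the 12
  # off-diagonal recurrent points lie on lines >= 2
  expect_equal(m$determinism, 10 / 12)

  see <- rqaMetrics(recurrenceMatrix(encodeText("see")))
  expect_equal(see$recurrence_rate, 5 / 9)
  expect_equal(see$determinism, 0)
  expect_error(rqaMetrics(id3, lMin = 1), "lMin")
})

test_that("PNG export writes an 8-bit grayscale file", {
  rp <- recurrenceMatrix(standardizeLength(encodeText("cookie jar"), 64))
  img <- asRecurrenceImage(rp, 32)
  f <- tempfile(fileext = ".png")
  writeRecurrencePng(img, f)
  back <- png::readPNG(f)
  expect_equal(dim(back), c(32L, 32L))
  expect_equal(back, recurrenceValues(img), tolerance = 1 / 255)
})
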
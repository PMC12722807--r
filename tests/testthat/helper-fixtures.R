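# fixtures are built in code at test time; nothing is read from disk

chatFixture <- function(lines) paste(lines, collapse = "\n")

# small generated CHAT corpus on disk (cached per session)
tinyCorpusDir <- local({
  cache <- new.env()
  function(n = 6L, participants = 4L, seed = 7L) {
    key <- paste(n, participants, seed, sep = "_")
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("corpus_", key))
      generateCorpus(dir, n, n, participantsPerClass = participants,
                     seed = seed)
      cache[[key]] <- dir
    }
    cache[[key]]
  }
})

# in-memory corpus with class-exclusive keywords for the TF-IDF baseline
keywordCorpus <- function(nPerClass = 30L, participantsPerClass = 10L,
                          seed = 5L) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  common <- c("the", "boy", "is", "on", "a", "stool", "and", "mother",
              "washes", "dishes")
  withr_seed({
    mk <- function(marker, n) vapply(seq_len(n), function(i)
      paste(c(sample(common, 8, replace = TRUE), marker,
              sample(common, 4, replace = TRUE)), collapse = " "),
      character(1))
    texts <- c(mk("window", nPerClass), mk("overflow", nPerClass))
  })
  corpusFromTexts(
    texts,
    labels = rep(c("control", "impaired"), each = nPerClass),
    participant_id = c(
      paste0("kc", rep_len(seq_len(participantsPerClass), nPerClass)),
      paste0("ki", rep_len(seq_len(participantsPerClass), nPerClass))),
    transcript_id = paste0("kw", seq_len(2 * nPerClass)))
}

# synthetic labeled recurrence-like images with controllable contrast
patternImages <- function(nPerClass, noise = 0.05, seed = 1L) {
  set.seed(seed)
  mk <- function(kind) {
    base <- matrix(0, 128, 128)
    if (kind == "blocky") {
      for (s in seq(1, 128, by = 32)) base[s:(s + 15), s:(s + 15)] <- 1
    } else {
      base[outer(seq_len(128), seq_len(128),
                 function(i, j) abs(i - j) < 6)] <- 1
    }
    pmin(pmax(base + matrix(rnorm(128 * 128, 0, noise), 128, 128), 0), 1)
  }
  images <- c(replicate(nPerClass, mk("blocky"), simplify = FALSE),
              replicate(nPerClass, mk("banded"), simplify = FALSE))
  list(images = images,
       labels = rep(c("control", "impaired"), each = nPerClass))
}

# brute-force recurrence oracle: direct double loop over Eq.-style rule
bruteRecurrence <- function(codes, eps = NULL) {
  n <- length(codes)
  R <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      R[i, j] <- if (is.null(eps)) as.numeric(codes[i] == codes[j])
                 else as.numeric(abs(codes[i] - codes[j]) <= eps)
    }
  }
  R
}
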
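#' Default scene vocabulary for the synthetic generator
#'
#' Nouns and verbs of the standard kitchen picture-description scene.
#'
#' @return character vector of 15 words.
#' @export
cookieTheftVocabulary <- function() {
  c("boy", "girl", "mother", "cookie", "jar", "stool", "sink", "water",
    "plate", "reach", "fall", "wash", "overflow", "take", "dry")
}

#' Synthetic-corpus class profile
#'
#' Generator parameters for one class of picture-description transcripts.
#' The default profiles emulate the fluency contrast between healthy
#' controls and cognitively impaired speakers: the impaired profile has
#' strictly higher filler, repetition, pause and fragmentation rates and
#' shorter utterances.
#'
#' @param label `"control"` or `"impaired"`.
#' @param fillerRate probability per word of inserting a filler (`uh`/`um`).
#' @param repetitionRate probability per word of immediate repetition.
#' @param pauseRate probability per word boundary of a pause mark `(.)`.
#' @param fragmentRate probability an utterance is truncated early.
#' @param wordsPerUtterance integer range `c(lo, hi)`.
#' @param utteranceCount integer range `c(lo, hi)` (default 8-14).
#' @param vocabulary scene word list (>= 10 words).
#' @param chatMarkup emit genuine CHAT markup (`&-uh`, `(.)`, `+...`);
#'   `FALSE` gives plain words for unit tests.
#' @return a [ClassProfile-class].
#' @export
classProfile <- function(label, fillerRate, repetitionRate, pauseRate,
                         fragmentRate, wordsPerUtterance,
                         utteranceCount = c(8L, 14L),
                         vocabulary = cookieTheftVocabulary(),
                         chatMarkup = TRUE) {
  new("ClassProfile", label = label, fillerRate = fillerRate,
      repetitionRate = repetitionRate, pauseRate = pauseRate,
      fragmentRate = fragmentRate,
      wordsPerUtterance = as.integer(wordsPerUtterance),
      utteranceCount = as.integer(utteranceCount),
      vocabulary = vocabulary, chatMarkup = chatMarkup)
}

#' @rdname classProfile
#' @param contrast `"default"` for the standard profiles or `"mild"` for a
#'   narrower rate gap between the classes.
#' @export
defaultProfiles <- function(contrast = c("default", "mild")) {
  contrast <- match.arg(contrast)
  if (contrast == "default") {
    list(
      control = classProfile("control", fillerRate = 0.02,
                             repetitionRate = 0.01, pauseRate = 0.05,
                             fragmentRate = 0.05,
                             wordsPerUtterance = c(8L, 15L)),
      impaired = classProfile("impaired", fillerRate = 0.15,
                              repetitionRate = 0.10, pauseRate = 0.20,
                              fragmentRate = 0.25,
                              wordsPerUtterance = c(3L, 8L))
    )
  } else {
    list(
      control = classProfile("control", fillerRate = 0.04,
                             repetitionRate = 0.02, pauseRate = 0.08,
                             fragmentRate = 0.08,
                             wordsPerUtterance = c(7L, 13L)),
      impaired = classProfile("impaired", fillerRate = 0.08,
                              repetitionRate = 0.05, pauseRate = 0.12,
                              fragmentRate = 0.14,
                              wordsPerUtterance = c(5L, 10L))
    )
  }
}

sampleRange <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
}

#' Sample one synthetic CHAT transcript
#'
#' Emits a syntactically valid CHAT file: `@Begin`/`@End`, participant
#' declarations, and alternating `*INV` prompts and `*PAR` description
#' lines generated from the profile's disfluency rates. Consumes the
#' current R RNG stream, so it is deterministic under `set.seed()`.
#'
#' @param profile a [ClassProfile-class].
#' @return single string, the CHAT file content.
#' @export
sampleTranscript <- function(profile) {
  stopifnot(is(profile, "ClassProfile"))
  prompts <- c("tell me everything you see going on in this picture .",
               "anything else ?", "what is happening there ?",
               "go on .", "mhm .")
  nUtt <- sampleRange(profile@utteranceCount)
  lines <- c("@Begin", "@Languages:\teng",
             "@Participants:\tPAR Participant, INV Investigator")
  fillerTok <- function() {
    w <- sample(c("uh", "um"), 1L)
    if (profile@chatMarkup) paste0("&-", w) else w
  }
  pauseTok <- if (profile@chatMarkup) "(.)" else "."
  for (u in seq_len(nUtt)) {
    lines <- c(lines, paste0("*INV:\t", sample(prompts, 1L)))
    nWords <- sampleRange(profile@wordsPerUtterance)
    fragmented <- stats::runif(1) < profile@fragmentRate
    if (fragmented) nWords <- max(1L, sample.int(nWords, 1L))
    toks <- character(0)
    prev <- ""
    for (w in seq_len(nWords)) {
      if (stats::runif(1) < profile@fillerRate)
        toks <- c(toks, fillerTok())
      # never draw the same word twice in a row, so immediate repetition
      # is produced only by the repetition mechanism itself
      word <- sample(setdiff(profile@vocabulary, prev), 1L)
      prev <- word
      toks <- c(toks, word)
      if (stats::runif(1) < profile@repetitionRate)
        toks <- c(toks, word)
      if (stats::runif(1) < profile@pauseRate)
        toks <- c(toks, pauseTok)
    }
    term <- if (fragmented && profile@chatMarkup) "+..." else "."
    lines <- c(lines, paste0("*PAR:\t", paste(toks, collapse = " "),
                             " ", term))
  }
  paste(c(lines, "@End"), collapse = "\n")
}

#' Generate a two-class synthetic CHAT corpus on disk
#'
#' Writes `.cha` files, a `metadata.csv` matching the corpus loader's
#' schema, and a `manifest.json` recording all profile parameters and the
#' seed. Transcripts are dealt round-robin to participants, so some
#' participants contribute several transcripts and the grouped-CV logic is
#' genuinely exercised. Fully reproducible under `seed`.
#'
#' @param outdir output directory (created if needed).
#' @param nControl,nImpaired transcripts per class (default 60 each).
#' @param profiles list with elements `control` and `impaired`
#'   ([classProfile()]); default [defaultProfiles()].
#' @param participantsPerClass participants per class (default 40).
#' @param seed integer seed.
#' @return invisibly, list with `paths`, `metadata` (data.frame) and
#'   `manifest`.
#' @export
generateCorpus <- function(outdir, nControl = 60L, nImpaired = 60L,
                           profiles = defaultProfiles(),
                           participantsPerClass = 40L, seed = 1L) {
  stopifnot(nControl >= 1L, nImpaired >= 1L,
            participantsPerClass <= nControl,
            participantsPerClass <= nImpaired)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  plan <- data.frame(
    transcript_id = c(sprintf("ctl%03d", seq_len(nControl)),
                      sprintf("imp%03d", seq_len(nImpaired))),
    participant_id = c(
      sprintf("PC%03d", rep_len(seq_len(participantsPerClass), nControl)),
      sprintf("PI%03d", rep_len(seq_len(participantsPerClass), nImpaired))),
    label = rep(c("control", "impaired"), c(nControl, nImpaired)),
    stringsAsFactors = FALSE)
  texts <- withSeed(seed, {
    vapply(seq_len(nrow(plan)), function(i)
      sampleTranscript(profiles[[plan$label[i]]]), character(1))
  })
  paths <- file.path(outdir, paste0(plan$transcript_id, ".cha"))
  for (i in seq_along(paths)) writeLines(texts[i], paths[i])
  utils::write.csv(plan, file.path(outdir, "metadata.csv"),
                   row.names = FALSE)
  profileList <- function(p) list(
    label = p@label, filler_rate = p@fillerRate,
    repetition_rate = p@repetitionRate, pause_rate = p@pauseRate,
    fragment_rate = p@fragmentRate,
    words_per_utterance = p@wordsPerUtterance,
    utterance_count = p@utteranceCount, chat_markup = p@chatMarkup)
  manifest <- list(seed = seed, n_control = nControl,
                   n_impaired = nImpaired,
                   participants_per_class = participantsPerClass,
                   profiles = lapply(profiles, profileList))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(paths = paths, metadata = plan, manifest = manifest))
}

#' Load a generated corpus directory
#'
#' Convenience wrapper: reads `metadata.csv` and all `.cha` files written
#' by [generateCorpus()] through the standard loader.
#'
#' @param dir corpus directory.
#' @param policy a [CleaningPolicy-class].
#' @return a [TranscriptCorpus-class].
#' @export
loadCorpusDir <- function(dir, policy = cleaningPolicy()) {
  md <- utils::read.csv(file.path(dir, "metadata.csv"),
                        stringsAsFactors = FALSE)
  paths <- file.path(dir, paste0(md$transcript_id, ".cha"))
  loadCorpus(paths, md, policy)
}
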
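#' @useDynLib charRQA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Cleaning policy for CHAT main-tier utterances
#'
#' Controls which CHAT markup survives into the cleaned character stream.
#' The default keeps paralinguistic signal (fillers, pause marks rendered as
#' periods) while stripping analysis codes, so that character-level encoding
#' retains disfluency structure.
#'
#' @slot pauseToPeriod logical; replace CHAT pause marks `(.)`, `(..)`,
#'   `(...)` with a single `"."` so the pause survives as a symbol.
#' @slot keepFillers logical; keep `&-uh` / `&uh` filler tokens as their bare
#'   word (`uh`). If `FALSE` they are removed.
#' @slot stripEventCodes logical; delete square-bracket analysis codes
#'   (`[//]`, `[: text]`, ...) and `&=`-prefixed nonspeech events.
#' @slot stripRetraceMarks logical; drop angle-bracket retracing delimiters
#'   while keeping the retraced words.
#' @export
setClass("CleaningPolicy",
  representation(
    pauseToPeriod = "logical",
    keepFillers = "logical",
    stripEventCodes = "logical",
    stripRetraceMarks = "logical"
  ),
  prototype(
    pauseToPeriod = TRUE,
    keepFillers = TRUE,
    stripEventCodes = TRUE,
    stripRetraceMarks = TRUE
  )
)

#' Labeled transcript corpus
#'
#' One row per transcript: id, participant, class label and the cleaned
#' participant-only text. Multiple transcripts may share a participant;
#' grouped cross-validation keys on `participant_id`.
#'
#' @slot records data.frame with columns `transcript_id`, `participant_id`,
#'   `label` (one of `"control"`, `"impaired"`), `text`, `source_path`, and
#'   optional metadata columns (`age`, `gender`, `mmse`, `education`).
#' @export
setClass("TranscriptCorpus", representation(records = "data.frame"))

setValidity("TranscriptCorpus", function(object) {
  rec <- object@records
  need <- c("transcript_id", "participant_id", "label", "text", "source_path")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(rec$transcript_id))
    return("duplicate transcript_id in corpus")
  if (!all(rec$label %in% c("control", "impaired")))
    return("labels must be 'control' or 'impaired'")
  if (any(!nzchar(rec$participant_id)))
    return("participant_id must be non-empty")
  TRUE
})

#' Character-to-integer alphabet
#'
#' Injective map from characters to positive integer codes. Code 0 is the
#' pad marker and is never assigned to a character; characters outside the
#' alphabet map to `unknownCode`.
#'
#' @slot mapping named integer vector (names are single characters).
#' @slot padCode integer, always 0.
#' @slot unknownCode positive integer used for out-of-alphabet characters.
#' @export
setClass("AlphabetMap",
  representation(mapping = "integer", padCode = "integer",
                 unknownCode = "integer"))

setValidity("AlphabetMap", function(object) {
  m <- object@mapping
  if (is.null(names(m)) || any(!nzchar(names(m))))
    return("mapping must be a named integer vector")
  if (anyDuplicated(m)) return("mapping must be injective")
  if (any(m <= 0L)) return("0 (pad) must never be assigned to a character")
  if (object@padCode != 0L) return("padCode must be 0")
  if (object@unknownCode %in% m)
    return("unknownCode must not collide with a mapped character")
  TRUE
})

#' Integer-coded character sequence
#'
#' @slot codes integer vector; pad code 0 may occur only as a contiguous
#'   suffix.
#' @slot effectiveLength number of leading non-pad symbols.
#' @slot transcriptId source transcript id (may be "").
#' @export
setClass("SymbolSequence",
  representation(codes = "integer", effectiveLength = "integer",
                 transcriptId = "character"))

setValidity("SymbolSequence", function(object) {
  codes <- object@codes
  n <- object@effectiveLength
  if (length(codes) < 1L) return("codes must be non-empty")
  if (n < 1L || n > length(codes))
    return("effectiveLength must be in [1, length(codes)]")
  if (any(codes[seq_len(n)] == 0L))
    return("pad code 0 inside the effective prefix")
  if (n < length(codes) && any(codes[(n + 1L):length(codes)] != 0L))
    return("non-pad code inside the pad suffix")
  TRUE
})

#' Binary recurrence plot of a symbol sequence
#'
#' Square 0/1 matrix marking time pairs (i, j) at which the sequence repeats
#' a symbol (`exact` mode) or at which the coded states lie within the
#' distance threshold epsilon (`heaviside` mode). Rows/columns in the pad
#' suffix are forced to 0.
#'
#' @slot matrix square numeric 0/1 matrix.
#' @slot effectiveLength size of the unpadded leading block.
#' @slot epsilon distance threshold used (0 in exact mode).
#' @slot mode `"exact"` or `"heaviside"`.
#' @slot transcriptId source transcript id.
#' @export
setClass("RecurrencePlot",
  representation(matrix = "matrix", effectiveLength = "integer",
                 epsilon = "numeric", mode = "character",
                 transcriptId = "character"))

setValidity("RecurrencePlot", function(object) {
  M <- object@matrix
  n <- object@effectiveLength
  if (nrow(M) != ncol(M)) return("matrix must be square")
  if (!all(M %in% c(0, 1))) return("entries must be 0/1")
  if (!isSymmetric(unname(M))) return("matrix must be symmetric")
  if (n > nrow(M)) return("effectiveLength exceeds matrix size")
  if (any(diag(M)[seq_len(n)] != 1))
    return("unit diagonal required on the unpadded block")
  if (n < nrow(M)) {
    pad <- (n + 1L):nrow(M)
    if (any(M[pad, ] != 0) || any(M[, pad] != 0))
      return("pad region must be all zero")
  }
  if (!object@mode %in% c("exact", "heaviside"))
    return("mode must be 'exact' or 'heaviside'")
  TRUE
})

#' Fixed-size normalized recurrence image
#'
#' @slot pixels numeric matrix in `[0, 1]`, by default 128 x 128.
#' @slot transcriptId source transcript id.
#' @export
setClass("RecurrenceImage",
  representation(pixels = "matrix", transcriptId = "character"))

setValidity("RecurrenceImage", function(object) {
  p <- object@pixels
  if (nrow(p) != ncol(p)) return("pixels must be square")
  if (min(p) < 0 || max(p) > 1) return("pixels must lie in [0, 1]")
  TRUE
})

#' Twin-branch convolutional encoder
#'
#' Fixed architecture: input 128 x 128 x 1; Conv 32 filters 3x3 ReLU;
#' MaxPool 2x2; Conv 64 filters 3x3 ReLU; MaxPool 2x2; Flatten; Dense 128
#' ReLU. Both Siamese branches share these weights by construction: there is
#' a single parameter set.
#'
#' @slot weights named list of parameter matrices/vectors
#'   (`W1`, `b1`, `W2`, `b2`, `W3`, `b3`).
#' @slot inputSize image side length (128).
#' @slot embedDim embedding dimension (128).
#' @slot trained logical; has `trainSiamese()` been run.
#' @slot history data.frame of per-epoch mean training loss (empty until
#'   trained).
#' @slot config list echoing the training configuration (margin, lr, ...).
#' @export
setClass("SiameseEncoder",
  representation(weights = "list", inputSize = "integer",
                 embedDim = "integer", trained = "logical",
                 history = "data.frame", config = "list"))

#' Participant-grouped fold assignment
#'
#' Every participant (and therefore every one of their transcripts) belongs
#' to exactly one of `k` folds; assignment is class-stratified at the
#' participant level.
#'
#' @slot fold named integer vector: fold index (1..k) per participant_id.
#' @slot k number of folds.
#' @export
setClass("FoldAssignment",
  representation(fold = "integer", k = "integer"))

setValidity("FoldAssignment", function(object) {
  if (is.null(names(object@fold))) return("fold must be named by participant")
  if (anyDuplicated(names(object@fold)))
    return("a participant may appear in exactly one fold")
  if (any(object@fold < 1L) || any(object@fold > object@k))
    return("fold indices must lie in 1..k")
  TRUE
})

#' Cross-validation report
#'
#' Fold-level AUCs with summary statistics and a nonparametric bootstrap
#' confidence interval for the mean.
#'
#' @slot foldAucs numeric vector of per-fold test AUCs.
#' @slot mean,std,min,max summary statistics (std is the sample, n-1,
#'   standard deviation).
#' @slot ciLow,ciHigh bootstrap percentile bounds for the mean AUC.
#' @slot config list fingerprint of the run configuration.
#' @export
setClass("CVReport",
  representation(foldAucs = "numeric", mean = "numeric", std = "numeric",
                 min = "numeric", max = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", config = "list"))

setValidity("CVReport", function(object) {
  a <- object@foldAucs
  if (any(a < 0 | a > 1)) return("fold AUCs must lie in [0, 1]")
  if (object@min > object@mean || object@mean > object@max)
    return("min <= mean <= max violated")
  if (object@ciLow > object@ciHigh) return("ciLow must be <= ciHigh")
  TRUE
})

#' Synthetic-corpus class profile
#'
#' Per-class generator parameters for the two-class CHAT corpus generator.
#' Rates are per-word (filler, repetition), per-word-boundary (pause) or
#' per-utterance (fragment) probabilities.
#'
#' @slot label `"control"` or `"impaired"`.
#' @slot fillerRate,repetitionRate,pauseRate,fragmentRate probabilities in
#'   `[0, 1]`.
#' @slot wordsPerUtterance integer range `c(lo, hi)`.
#' @slot utteranceCount integer range `c(lo, hi)`.
#' @slot vocabulary character vector of scene words (>= 10).
#' @slot chatMarkup logical; emit genuine CHAT markup (`&-uh`, `(.)`) rather
#'   than plain words.
#' @export
setClass("ClassProfile",
  representation(label = "character", fillerRate = "numeric",
                 repetitionRate = "numeric", pauseRate = "numeric",
                 fragmentRate = "numeric", wordsPerUtterance = "integer",
                 utteranceCount = "integer", vocabulary = "character",
                 chatMarkup = "logical"))

setValidity("ClassProfile", function(object) {
  rates <- c(object@fillerRate, object@repetitionRate, object@pauseRate,
             object@fragmentRate)
  if (any(rates < 0 | rates > 1)) return("rates must lie in [0, 1]")
  if (length(object@vocabulary) < 10L)
    return("vocabulary must have at least 10 words")
  if (length(object@wordsPerUtterance) != 2L ||
      diff(object@wordsPerUtterance) < 0L)
    return("wordsPerUtterance must be a non-empty range c(lo, hi)")
  if (length(object@utteranceCount) != 2L || diff(object@utteranceCount) < 0L)
    return("utteranceCount must be a non-empty range c(lo, hi)")
  TRUE
})
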
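#' Accessors
#'
#' Small accessor generics for the package's S4 containers, so downstream
#' code never reaches into slots.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("corpusRecords", function(x) standardGeneric("corpusRecords"))

#' @rdname accessors
#' @export
setMethod("corpusRecords", "TranscriptCorpus", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname accessors
#' @export
setMethod("classCounts", "TranscriptCorpus", function(x)
  table(factor(x@records$label, levels = c("control", "impaired"))))

#' @rdname accessors
#' @export
setGeneric("symbolCodes", function(x) standardGeneric("symbolCodes"))

#' @rdname accessors
#' @export
setMethod("symbolCodes", "SymbolSequence", function(x) x@codes)

#' @rdname accessors
#' @export
setGeneric("effectiveLength", function(x) standardGeneric("effectiveLength"))

#' @rdname accessors
#' @export
setMethod("effectiveLength", "SymbolSequence", function(x) x@effectiveLength)

#' @rdname accessors
#' @export
setMethod("effectiveLength", "RecurrencePlot", function(x) x@effectiveLength)

#' @rdname accessors
#' @export
setGeneric("recurrenceValues", function(x) standardGeneric("recurrenceValues"))

#' @rdname accessors
#' @export
setMethod("recurrenceValues", "RecurrencePlot", function(x) x@matrix)

#' @rdname accessors
#' @export
setMethod("recurrenceValues", "RecurrenceImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("foldAucs", function(x) standardGeneric("foldAucs"))

#' @rdname accessors
#' @export
setMethod("foldAucs", "CVReport", function(x) x@foldAucs)

#' @rdname accessors
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))

#' @rdname accessors
#' @export
setMethod("lossHistory", "SiameseEncoder", function(x) x@history)

#' Fold index per transcript
#'
#' Expands a participant-level [FoldAssignment] to one fold index per corpus
#' record (all of a participant's transcripts share the participant's fold).
#'
#' @param x a [FoldAssignment].
#' @param corpus a [TranscriptCorpus].
#' @return integer vector of fold indices, one per corpus record.
#' @export
setGeneric("transcriptFolds",
           function(x, corpus) standardGeneric("transcriptFolds"))

#' @rdname transcriptFolds
#' @export
setMethod("transcriptFolds", "FoldAssignment", function(x, corpus) {
  pid <- corpusRecords(corpus)$participant_id
  missing <- setdiff(unique(pid), names(x@fold))
  if (length(missing))
    stop("participants without a fold assignment: ",
         paste(missing, collapse = ", "))
  unname(x@fold[pid])
})

setMethod("show", "TranscriptCorpus", function(object) {
  cc <- classCounts(object)
  cat("TranscriptCorpus:", nrow(object@records), "transcripts,",
      length(unique(object@records$participant_id)), "participants\n")
  cat("  control:", cc[["control"]], " impaired:", cc[["impaired"]], "\n")
})

setMethod("show", "SymbolSequence", function(object) {
  cat("SymbolSequence [", object@transcriptId, "]: length ",
      length(object@codes), ", effective ", object@effectiveLength, "\n",
      sep = "")
})

setMethod("show", "RecurrencePlot", function(object) {
  cat("RecurrencePlot [", object@transcriptId, "]: ", nrow(object@matrix),
      "x", ncol(object@matrix), ", mode=", object@mode,
      ", effective=", object@effectiveLength, "\n", sep = "")
})

setMethod("show", "RecurrenceImage", function(object) {
  cat("RecurrenceImage [", object@transcriptId, "]: ", nrow(object@pixels),
      "x", ncol(object@pixels), ", range [",
      signif(min(object@pixels), 3), ", ", signif(max(object@pixels), 3),
      "]\n", sep = "")
})

setMethod("show", "SiameseEncoder", function(object) {
  cat("SiameseEncoder: 128x128x1 -> Conv32(3x3) -> Pool -> Conv64(3x3)",
      "-> Pool -> Dense", object@embedDim, "\n")
  cat("  trained:", object@trained,
      if (nrow(object@history)) paste0("(", nrow(object@history), " epochs, ",
        "final loss ", signif(utils::tail(object@history$loss, 1), 4), ")"
      ) else "", "\n")
})

setMethod("show", "FoldAssignment", function(object) {
  cat("FoldAssignment: k =", object@k, ",", length(object@fold),
      "participants\n")
  print(table(object@fold))
})

setMethod("show", "CVReport", function(object) {
  cat("CVReport (", length(object@foldAucs), " folds)\n", sep = "")
  cat("  fold AUCs:", paste(sprintf("%.3f", object@foldAucs),
                            collapse = ", "), "\n")
  cat(sprintf("  mean %.3f  std %.3f  min %.3f  max %.3f\n",
              object@mean, object@std, object@min, object@max))
  cat(sprintf("  95%% bootstrap CI [%.3f, %.3f]\n",
              object@ciLow, object@ciHigh))
})
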
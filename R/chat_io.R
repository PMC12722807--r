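#' Construct a cleaning policy
#'
#' @param pauseToPeriod replace CHAT pause marks `(.)`, `(..)`, `(...)` with
#'   a single `"."` (default `TRUE`); with `FALSE` pause marks are deleted.
#' @param keepFillers keep `&-uh`-style fillers as bare words (default
#'   `TRUE`).
#' @param stripEventCodes delete `[...]` analysis codes and `&=` nonspeech
#'   events (default `TRUE`).
#' @param stripRetraceMarks drop `<`/`>` retracing delimiters, keeping the
#'   retraced words (default `TRUE`).
#' @return a [CleaningPolicy-class] object.
#' @export
cleaningPolicy <- function(pauseToPeriod = TRUE, keepFillers = TRUE,
                           stripEventCodes = TRUE, stripRetraceMarks = TRUE) {
  new("CleaningPolicy", pauseToPeriod = pauseToPeriod,
      keepFillers = keepFillers, stripEventCodes = stripEventCodes,
      stripRetraceMarks = stripRetraceMarks)
}

#' Clean one CHAT main-tier utterance
#'
#' Applies the cleaning policy to the text following a `*SPK:` prefix:
#' timing bullets and control characters are always stripped; pause marks
#' become `"."`; square-bracket analysis codes and `&=` events are deleted;
#' angle-bracket retracing delimiters are dropped (words kept); fillers
#' `&-uh` / `&uh` are kept as bare words; trailing-off and interruption
#' terminators (`+...`, `+/.`, ...) become `"."`; whitespace is collapsed.
#'
#' @param raw character vector of utterance strings (content after the tier
#'   prefix).
#' @param policy a [CleaningPolicy-class]; default [cleaningPolicy()].
#' @return character vector of cleaned utterances.
#' @examples
#' cleanUtterance("&uh the <the boy> [//] boy")  # "uh the the boy boy"
#' cleanUtterance("the cookie (.) jar")          # "the cookie . jar"
#' @export
cleanUtterance <- function(raw, policy = cleaningPolicy()) {
  stopifnot(is.character(raw))
  x <- raw
  # timing bullets are 0x15-delimited in CHA files; also drop stray controls
  x <- gsub("\x15[^\x15]*\x15", " ", x, useBytes = TRUE)
  x <- gsub("[[:cntrl:]]", " ", x)
  if (policy@pauseToPeriod) {
    x <- gsub("\\(\\.{1,3}\\)", " . ", x)
  } else {
    x <- gsub("\\(\\.{1,3}\\)", " ", x)
  }
  if (policy@stripEventCodes) {
    # innermost-first so nested codes like [* [: x]] resolve; cap iterations
    for (i in 1:8) {
      x2 <- gsub("\\[[^][]*\\]", " ", x)
      if (identical(x2, x)) break
      x <- x2
    }
    bad <- grepl("[][]", x)
    if (any(bad)) {
      warning("unbalanced square brackets; literal text kept")
      x[bad] <- gsub("[][]", " ", x[bad])
    }
    x <- gsub("&=\\S+", " ", x)
  }
  if (policy@stripRetraceMarks) x <- gsub("[<>]", " ", x)
  if (policy@keepFillers) {
    x <- gsub("&[-+]?(\\w)", "\\1", x)
  } else {
    x <- gsub("&[-+]?\\S+", " ", x)
  }
  # utterance terminators: trailing-off / interruption codes end the
  # utterance, so they are mapped to "." to keep the boundary symbol
  x <- gsub("\\+(\\.\\.\\.|\\.\\.|//?\\.|//?\\?|\"/?\\.)", " . ", x)
  x <- gsub("\\+[<^,]", " ", x)      # quick-uptake / self-completion links
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Parse a CHAT transcript, isolating participant speech
#'
#' Reads CHAT-format content, keeps only main-tier utterances of the
#' participant speaker code (interviewer tiers, dependent `%` tiers and `@`
#' headers are dropped), cleans each utterance per the policy, and joins
#' them in file order with single spaces.
#'
#' @param x path to a `.cha` file, or the raw file content as a single
#'   string / character vector of lines.
#' @param policy a [CleaningPolicy-class].
#' @param speaker participant speaker code (default `"PAR"`).
#' @return single string of cleaned participant-only text.
#' @export
parseChat <- function(x, policy = cleaningPolicy(), speaker = "PAR") {
  lines <- if (length(x) == 1L && file.exists(x)) {
    tryCatch(readLines(x, warn = FALSE, encoding = "UTF-8"),
             error = function(e) stop("parse error reading '", x, "': ",
                                      conditionMessage(e)))
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  if (!any(grepl("^\\*", lines)))
    stop("parse error: no main tier (*SPK:) line found")
  # continuation lines (leading tab/space) attach to the previous tier
  owner <- character(length(lines))
  cur <- ""
  content <- character(length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^[*%@]", ln)) {
      m <- regmatches(ln, regexec("^([*%@])([^:]*):?\\s*(.*)$", ln))[[1]]
      cur <- if (m[2] == "*") m[3] else ""
      content[i] <- m[4]
      owner[i] <- cur
    } else if (grepl("^[\t ]", ln) && nzchar(cur)) {
      owner[i] <- cur
      content[i] <- ln
    } else {
      cur <- ""
    }
  }
  keep <- owner == speaker
  if (!any(keep))
    stop("empty transcript: no *", speaker, " tier found")
  utts <- cleanUtterance(content[keep], policy)
  # continuation fragments merge into their utterance via the same join
  out <- paste(utts[nzchar(utts)], collapse = " ")
  if (!nzchar(out))
    stop("empty transcript: *", speaker,
         " tiers contain no text after cleaning")
  out
}

#' Load a labeled transcript corpus
#'
#' Parses each CHAT file and joins it with a metadata table to build a
#' [TranscriptCorpus-class]. Transcript ids default to file basenames
#' without the `.cha` extension and must each appear in `metadata`.
#'
#' @param paths character vector of `.cha` file paths.
#' @param metadata data.frame with columns `transcript_id`,
#'   `participant_id`, `label` and optionally `age`, `gender`, `mmse`,
#'   `education`.
#' @param policy a [CleaningPolicy-class].
#' @param speaker participant speaker code.
#' @return a [TranscriptCorpus-class].
#' @export
loadCorpus <- function(paths, metadata, policy = cleaningPolicy(),
                       speaker = "PAR") {
  stopifnot(is.data.frame(metadata))
  need <- c("transcript_id", "participant_id", "label")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  ids <- sub("\\.cha$", "", basename(paths))
  if (anyDuplicated(ids))
    stop("duplicate transcript_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing <- setdiff(ids, metadata$transcript_id)
  if (length(missing))
    stop("no metadata label for transcript_id: ",
         paste(missing, collapse = ", "))
  md <- metadata[match(ids, metadata$transcript_id), , drop = FALSE]
  bad <- !md$label %in% c("control", "impaired")
  if (any(bad))
    stop("label not in {control, impaired} for: ",
         paste(ids[bad], collapse = ", "))
  texts <- vapply(paths, parseChat, character(1), policy = policy,
                  speaker = speaker, USE.NAMES = FALSE)
  rec <- data.frame(transcript_id = ids,
                    participant_id = as.character(md$participant_id),
                    label = md$label, text = texts,
                    source_path = as.character(paths),
                    stringsAsFactors = FALSE)
  for (col in intersect(c("age", "gender", "mmse", "education"), names(md)))
    rec[[col]] <- md[[col]]
  new("TranscriptCorpus", records = rec)
}

#' Assemble a corpus directly from texts (no files)
#'
#' Convenience constructor used by tests and by pipelines that already hold
#' cleaned texts in memory.
#'
#' @param texts character vector of cleaned participant texts.
#' @param labels character vector in `{control, impaired}`.
#' @param participant_id participant ids (default: one per text).
#' @param transcript_id transcript ids (default: `t1`, `t2`, ...).
#' @return a [TranscriptCorpus-class].
#' @export
corpusFromTexts <- function(texts, labels,
                            participant_id = paste0("p", seq_along(texts)),
                            transcript_id = paste0("t", seq_along(texts))) {
  new("TranscriptCorpus", records = data.frame(
    transcript_id = transcript_id,
    participant_id = as.character(participant_id),
    label = labels, text = texts, source_path = "",
    stringsAsFactors = FALSE))
}

#' Write a corpus table to CSV
#'
#' @param corpus a [TranscriptCorpus-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCorpusCsv <- function(corpus, path) {
  utils::write.csv(corpusRecords(corpus), path, row.names = FALSE)
  invisible(path)
}
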
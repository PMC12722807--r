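#' Default character alphabet
#'
#' Fixed injective mapping: `a`..`z` -> 1..26, space -> 27, `.` -> 28,
#' then a deterministic extension for common punctuation and digits
#' (`,` -> 29, `'` -> 30, `?` -> 31, `-` -> 32, `0`..`9` -> 33..42). Any
#' other character maps to the reserved unknown code 43. Code 0 is the pad
#' marker.
#'
#' @return an [AlphabetMap-class].
#' @examples
#' alphabetLookup(defaultAlphabet(), c("a", " ", "."))  # 1 27 28
#' @export
defaultAlphabet <- function() {
  chars <- c(letters, " ", ".", ",", "'", "?", "-", as.character(0:9))
  mapping <- stats::setNames(as.integer(seq_along(chars)), chars)
  new("AlphabetMap", mapping = mapping, padCode = 0L,
      unknownCode = 43L)
}

#' @rdname defaultAlphabet
#' @param alphabet an [AlphabetMap-class].
#' @param chars character vector of single characters.
#' @export
alphabetLookup <- function(alphabet, chars) {
  idx <- match(chars, names(alphabet@mapping))
  out <- alphabet@mapping[idx]
  out[is.na(idx)] <- alphabet@unknownCode
  unname(out)
}

normalizeText <- function(text, lowercase = TRUE) {
  x <- stringi::stri_trans_nfc(text)
  if (lowercase) x <- stringi::stri_trans_tolower(x)
  x
}

#' Encode text as an integer symbol sequence
#'
#' Characters of the NFC-normalized, lowercase-folded text are mapped
#' one-to-one to integer codes; the result carries no padding.
#'
#' @param text a single string.
#' @param alphabet an [AlphabetMap-class].
#' @param transcriptId id stored on the sequence.
#' @param lowercase fold case before mapping (default `TRUE`).
#' @return a [SymbolSequence-class].
#' @examples
#' symbolCodes(encodeText("um I see a boy"))
#' # 21 13 27 9 27 19 5 5 27 1 27 2 15 25
#' @export
encodeText <- function(text, alphabet = defaultAlphabet(),
                       transcriptId = "", lowercase = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- normalizeText(text, lowercase)
  if (!nzchar(x)) stop("nothing to encode")
  chars <- strsplit(x, "")[[1]]
  codes <- alphabetLookup(alphabet, chars)
  new("SymbolSequence", codes = codes,
      effectiveLength = length(codes), transcriptId = transcriptId)
}

#' Standardize sequence length by post-padding / end-truncation
#'
#' Shorter sequences are padded at the end with the pad code 0 (so the
#' informative initial portion is untouched); longer sequences are truncated
#' at the end.
#'
#' @param seq a [SymbolSequence-class].
#' @param targetLength positive integer.
#' @return a [SymbolSequence-class] of length `targetLength` with
#'   `effectiveLength = min(original, targetLength)`.
#' @export
standardizeLength <- function(seq, targetLength = 512L) {
  stopifnot(is(seq, "SymbolSequence"), targetLength >= 1L)
  targetLength <- as.integer(targetLength)
  n <- seq@effectiveLength
  codes <- seq@codes[seq_len(n)]
  if (n >= targetLength) {
    codes <- codes[seq_len(targetLength)]
    eff <- targetLength
  } else {
    codes <- c(codes, integer(targetLength - n))
    eff <- n
  }
  new("SymbolSequence", codes = codes, effectiveLength = eff,
      transcriptId = seq@transcriptId)
}

#' Decode a symbol sequence back to text
#'
#' Applies the inverse alphabet mapping to the non-pad prefix; the pad
#' suffix is dropped.
#'
#' @param seq a [SymbolSequence-class].
#' @param alphabet an [AlphabetMap-class].
#' @return the decoded string.
#' @export
decodeSymbols <- function(seq, alphabet = defaultAlphabet()) {
  stopifnot(is(seq, "SymbolSequence"))
  codes <- seq@codes[seq_len(seq@effectiveLength)]
  idx <- match(codes, alphabet@mapping)
  bad <- which(is.na(idx) & codes != alphabet@unknownCode)
  if (length(bad))
    stop("code outside alphabet image at position ", bad[1])
  chars <- names(alphabet@mapping)[idx]
  chars[is.na(idx)] <- "\uFFFD"  # unknown code has no unique preimage
  paste(chars, collapse = "")
}

#' Serialize symbol sequences to disk
#'
#' Writes codes as a plain CSV (one row per sequence, columns are
#' positions) with a JSON sidecar recording the alphabet fingerprint,
#' target length and transcript ids.
#'
#' @param seqs list of [SymbolSequence-class] of equal length.
#' @param path output CSV path (sidecar gets extension `.json`).
#' @return `path`, invisibly.
#' @export
writeSequences <- function(seqs, path) {
  stopifnot(length(seqs) > 0)
  lens <- vapply(seqs, function(s) length(s@codes), integer(1))
  if (length(unique(lens)) != 1L)
    stop("sequences must share one standardized length")
  mat <- do.call(rbind, lapply(seqs, symbolCodes))
  utils::write.table(mat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- list(
    transcript_id = vapply(seqs, function(s) s@transcriptId, character(1)),
    effective_length = vapply(seqs, effectiveLength, integer(1)),
    target_length = unique(lens),
    alphabet_hash = alphabetHash(defaultAlphabet())
  )
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path),
                                       ".json"), auto_unbox = TRUE)
  invisible(path)
}

alphabetHash <- function(alphabet) {
  s <- paste(names(alphabet@mapping), alphabet@mapping,
             collapse = ";", sep = "=")
  # small stable fingerprint; enough to detect alphabet drift between runs
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1000000007
}
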
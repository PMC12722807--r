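# evaluate expr under a temporary RNG seed, restoring the caller's state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  set.seed(seed)
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  expr
}

#' ROC-AUC by rank statistic
#'
#' Probability that a randomly chosen positive is scored above a randomly
#' chosen negative, computed from midranks (ties contribute 1/2).
#'
#' @param scores numeric scores, larger meaning more likely positive.
#' @param labels logical/0-1/character vector; `positive` names the
#'   positive class for character labels.
#' @param positive positive class label (default `"impaired"`).
#' @return AUC in `[0, 1]`.
#' @export
aucRank <- function(scores, labels, positive = "impaired") {
  pos <- if (is.character(labels) || is.factor(labels))
    as.character(labels) == positive else as.logical(labels)
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  if (nPos == 0 || nNeg == 0)
    stop("AUC needs both classes present")
  r <- rank(scores)  # midranks
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
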
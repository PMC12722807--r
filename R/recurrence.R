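#' Distance threshold for recurrence
#'
#' Returns 0.1 times the population standard deviation of the non-pad
#' symbol codes. Padding zeros are excluded so that padding cannot shift
#' the threshold.
#'
#' @param seq a [SymbolSequence-class] with `effectiveLength >= 2`.
#' @return non-negative scalar threshold.
#' @export
epsilonThreshold <- function(seq) {
  stopifnot(is(seq, "SymbolSequence"))
  n <- seq@effectiveLength
  if (n < 2L) stop("degenerate sequence: effective length < 2")
  x <- as.numeric(seq@codes[seq_len(n)])
  0.1 * sqrt(mean((x - mean(x))^2))
}

#' Recurrence matrix of a symbol sequence
#'
#' In `exact` mode (the default) a pair (i, j) recurs iff the two symbols
#' are identical: recurrence is defined by symbolic equivalence, so the
#' arbitrary numeric spacing of the codes never enters. In `heaviside` mode
#' the step-function thresholding of the absolute code distance is applied,
#' with the threshold from [epsilonThreshold()] and the boundary convention
#' that a distance exactly equal to the threshold recurs. With integer codes
#' the two modes coincide whenever the threshold is below 1; a threshold at
#' or above 1 (where numeric adjacency of codes would leak in) triggers a
#' warning.
#'
#' Rows and columns in the pad suffix are forced to zero: a pad-pad block
#' would otherwise be a solid artificial recurrent square.
#'
#' @param seq a [SymbolSequence-class] with `effectiveLength >= 2`.
#' @param mode `"exact"` (default) or `"heaviside"`.
#' @return a [RecurrencePlot-class] over the full (padded) length.
#' @export
recurrenceMatrix <- function(seq, mode = c("exact", "heaviside")) {
  stopifnot(is(seq, "SymbolSequence"))
  mode <- match.arg(mode)
  n <- seq@effectiveLength
  if (n < 2L) stop("degenerate sequence: effective length < 2")
  N <- length(seq@codes)
  x <- as.numeric(seq@codes[seq_len(n)])
  if (mode == "exact") {
    eps <- 0
    R <- outer(x, x, "==") * 1
  } else {
    eps <- epsilonThreshold(seq)
    if (eps >= 1)
      warning("heaviside threshold ", signif(eps, 4),
              " >= 1: numerically adjacent codes will recur")
    R <- (abs(outer(x, x, "-")) <= eps) * 1
  }
  M <- matrix(0, N, N)
  M[seq_len(n), seq_len(n)] <- R
  new("RecurrencePlot", matrix = M, effectiveLength = n,
      epsilon = eps, mode = mode, transcriptId = seq@transcriptId)
}

# Sparse row-resampling weights mapping n input cells onto `size` output
# cells. "area": exact rectangle-overlap averaging; "bilinear": two-tap
# linear interpolation at cell centers; "nearest": single-tap pick.
resampleWeights <- function(n, size, interp) {
  W <- matrix(0, size, n)
  if (interp == "area") {
    scale <- n / size
    for (k in seq_len(size)) {
      lo <- (k - 1) * scale
      hi <- k * scale
      i0 <- floor(lo) + 1
      i1 <- ceiling(hi)
      for (i in i0:min(i1, n)) {
        ov <- min(hi, i) - max(lo, i - 1)
        if (ov > 0) W[k, i] <- ov / scale
      }
    }
  } else if (interp == "bilinear") {
    # align cell centers, clamping at the borders
    pos <- ((seq_len(size) - 0.5) * n / size) + 0.5
    for (k in seq_len(size)) {
      p <- min(max(pos[k], 1), n)
      i0 <- floor(p)
      i1 <- min(i0 + 1, n)
      f <- p - i0
      W[k, i0] <- W[k, i0] + (1 - f)
      W[k, i1] <- W[k, i1] + f
    }
  } else {
    idx <- pmin(pmax(ceiling((seq_len(size) - 0.5) * n / size), 1), n)
    W[cbind(seq_len(size), idx)] <- 1
  }
  W
}

#' Render a recurrence plot as a fixed-size normalized image
#'
#' Resamples the binary matrix to `size` x `size` and guarantees pixel
#' values in `[0, 1]`. Area averaging (the default) preserves local
#' recurrence density; bilinear and nearest are selectable. An all-zero
#' matrix maps to an all-zero image.
#'
#' @param plot a [RecurrencePlot-class].
#' @param size output side length (default 128).
#' @param interp `"area"`, `"bilinear"` or `"nearest"`.
#' @return a [RecurrenceImage-class].
#' @export
asRecurrenceImage <- function(plot, size = 128L,
                              interp = c("area", "bilinear", "nearest")) {
  stopifnot(is(plot, "RecurrencePlot"))
  interp <- match.arg(interp)
  if (size < 2L) stop("image size must be at least 2")
  M <- plot@matrix
  n <- nrow(M)
  if (n == size && interp == "nearest") {
    P <- M
  } else {
    W <- resampleWeights(n, as.integer(size), interp)
    P <- W %*% M %*% t(W)
  }
  # convex weights keep binary input inside [0,1]; clamp rounding residue
  P <- pmin(pmax(P, 0), 1)
  new("RecurrenceImage", pixels = P, transcriptId = plot@transcriptId)
}

#' Recurrence quantification diagnostics
#'
#' Summary statistics of the unpadded block of a recurrence plot:
#' recurrence rate (density of recurrent points), determinism (fraction of
#' off-main-diagonal recurrent points lying on diagonal runs of length at
#' least `lMin`), and the longest off-main-diagonal run. These are
#' diagnostics only; the embedding pipeline consumes the full image.
#'
#' @param plot a [RecurrencePlot-class].
#' @param lMin minimum diagonal-line length (default 2).
#' @return list with `recurrence_rate`, `determinism`, `longest_diagonal`.
#' @export
rqaMetrics <- function(plot, lMin = 2L) {
  stopifnot(is(plot, "RecurrencePlot"))
  if (lMin < 2L) stop("lMin must be at least 2")
  n <- plot@effectiveLength
  R <- plot@matrix[seq_len(n), seq_len(n), drop = FALSE]
  rr <- sum(R) / n^2
  totalOff <- 0
  onLines <- 0
  longest <- 0L
  for (k in seq_len(n - 1)) {          # offsets 1..n-1; symmetry doubles
    d <- R[cbind(seq_len(n - k), seq_len(n - k) + k)]
    runs <- rle(d)
    recLens <- runs$lengths[runs$values == 1]
    if (length(recLens)) {
      totalOff <- totalOff + 2 * sum(recLens)
      onLines <- onLines + 2 * sum(recLens[recLens >= lMin])
      longest <- max(longest, max(recLens))
    }
  }
  list(recurrence_rate = rr,
       determinism = if (totalOff > 0) onLines / totalOff else 0,
       longest_diagonal = as.integer(longest))
}

#' Write a recurrence image as an 8-bit grayscale PNG
#'
#' @param image a [RecurrenceImage-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRecurrencePng <- function(image, path) {
  png::writePNG(recurrenceValues(image), path)
  invisible(path)
}
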
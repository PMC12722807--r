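---
title: "Symbolic recurrence embeddings of speech transcripts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symbolic recurrence embeddings of speech transcripts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(charRQA)
```

## The problem and the model

Connected speech carries early markers of cognitive decline: hesitations,
fillers, word repetitions, pauses and fragmented utterances accumulate
before scores on screening instruments such as the MMSE move. `charRQA`
implements a character-level, nonlinear-dynamics view of this signal for
picture-description transcripts in CHAT format.

The pipeline has four stages.

1. **Symbolic encoding.** Cleaned participant-only text is mapped
   character by character to integer codes (`a`..`z` to 1..26, space to
   27, `.` to 28, a fixed extension for other punctuation and digits).
   The integers are symbolic indices, not magnitudes: no semantics is
   attached to their spacing. Sequences are standardized to a common
   length by end-padding with the reserved code 0 or end-truncation, so
   the information-rich opening of each description is preserved.
2. **Recurrence plots.** A sequence \(x_1,\dots,x_N\) becomes a binary
   matrix \(R_{ij} = \Theta(\varepsilon - \lVert x_i - x_j\rVert)\) with
   \(\Theta\) the Heaviside step and \(\varepsilon = 0.1\,\sigma\) (the
   population standard deviation of the non-pad codes). Because codes are
   integers, any \(\varepsilon < 1\) makes this identical to symbolic
   equivalence, \(R_{ij} = 1 \iff x_i = x_j\), which is the intended
   semantics; `recurrenceMatrix()` therefore defaults to the `exact` mode
   and warns whenever the `heaviside` mode's threshold reaches 1, where
   the arbitrary numeric adjacency of codes would start to leak into the
   plot. Diagonal line segments in the plot mark repeated character
   subsequences — repeated words, refrains, perseverations.
3. **Metric learning.** Plots are resampled to 128 x 128 images in
   \([0,1]\) and fed to a twin-branch (Siamese) convolutional encoder —
   Conv 32\@3x3/ReLU, MaxPool 2x2, Conv 64\@3x3/ReLU, MaxPool 2x2,
   Flatten, Dense 128/ReLU — with one shared parameter set. Training
   minimizes the contrastive loss
   \(L = (1-Y)\tfrac12 D^2 + Y\tfrac12\max(0, m - D)^2\)
   over labeled image pairs (\(Y=0\) same class, \(Y=1\) different;
   \(D\) the Euclidean embedding distance), with margin \(m = 1\) and
   Adam at learning rate 0.001.
4. **Validation.** Embeddings feed a gradient-boosted tree classifier
   (regularized additive-tree objective) under participant-grouped,
   class-stratified 5-fold cross-validation; fold-level ROC-AUCs are
   summarized with a 10,000-resample percentile bootstrap of the mean. A
   word-level TF-IDF + ridge-logistic baseline runs under the identical
   fold assignment for comparison.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `targetLength` | 512 characters | standardized sequence length; most picture descriptions fit without truncation while keeping the \(N \times N\) plot tractable |
| `mode` | `"exact"` | recurrence rule; `"heaviside"` reproduces the thresholded form |
| `size`, `interp` | 128, `"area"` | image side and resampling kernel; area averaging preserves local recurrence density, nearest/bilinear are selectable |
| `margin` | 1.0 | contrastive margin (dimensionless, embedding units) |
| `learningRate` | 0.001 | Adam step size |
| `batchSize`, `epochs` | 32, 20 | minibatch pairs and maximum passes; early stop after 5 epochs without a 1e-4 improvement of the monitored loss |
| `valFraction` | 0.2 | fraction of training-fold participants held out to monitor encoder validation loss (see below) |
| `pairsPerImage` | 4 | sampled training pairs per training image, balanced between same- and different-class |
| `k`, `B` | 5, 10000 | outer folds; bootstrap resamples |
| classifier grid | eta {0.05, 0.1, 0.3} x depth {3, 5, 7} x lambda {0, 1, 10} | searched by inner 3-fold CV AUC on training folds only |

The cleaning policy (`cleaningPolicy()`) decides which CHAT markup
survives into the character stream. The default keeps the paralinguistic
signal the method targets — fillers are kept as bare words, pause marks
`(.)`/`(..)`/`(...)` become a literal `"."` so pauses survive encoding —
and strips analysis codes (square brackets, `&=` events) and retracing
delimiters while keeping retraced words. Trailing-off terminators
(`+...`) also map to `"."` so utterance boundaries stay visible. Each
rule is a policy switch, so stricter dialects are selectable.

## Design choices where the design was open

- **Case folding.** The worked encoding example maps `I` inside an
  otherwise lowercase scheme; we fold to lowercase (switchable), which
  keeps the alphabet small and deterministic.
- **Padding vs. the threshold and the plot.** \(\varepsilon\) is computed
  from the population standard deviation of the *non-pad* codes only, and
  all pad rows/columns of the plot are forced to zero. A pad-pad block
  would otherwise form a solid artificial recurrence square, and padded
  length would shift the threshold.
- **\(\Theta(0) = 1\).** The boundary case of the step function counts as
  a recurrence; irrelevant in exact mode, stated for determinism.
- **Per-fold encoder retraining.** Training the encoder once on all data
  would leak test-fold information into the embedding space. The default
  retrains per fold on training images only; `encoderScope = "single"`
  reproduces the optimistic single-fit variant for comparison.
- **The 80/20 split regularizes the encoder.** Within each training fold,
  20% of participants (grouped, class-stratified) are held out from
  encoder training; early stopping monitors the contrastive loss on pairs
  drawn from this validation split and the best-epoch weights are
  restored. Without it, the encoder memorizes the small per-fold training
  set — same-class training embeddings collapse to near-identical points
  while held-out images stay spread — and the downstream tree classifier,
  fit on collapsed coordinates, places split thresholds that do not
  transfer. Validation-monitored stopping halts training while the
  embedding still reflects class structure rather than image identity.
  The classifier is then fit on the embeddings of the *entire* training
  fold. Validation pairs (one quarter of the training-pair budget, drawn
  balanced from the held-out images) are used only for monitoring, never
  for gradient updates. With `valFraction = 0`, or when a fold is too
  small to hold out two images per class, stopping falls back to the
  training loss.
- **Grouped label permutation.** Permutation-null runs permute the
  participant-to-label map (not transcript labels), so each participant
  keeps a single coherent label and grouped stratification stays defined.
- **Loss conventions.** The pair label is \(Y=0\) for same-class pairs
  (distance term active) and \(Y=1\) for different-class (margin term),
  which is what the loss algebra forces. The distance entering the loss
  is the plain Euclidean norm; the loss squares it itself. At the
  non-differentiable point \(D=0, Y=1\) the zero subgradient is used.
- **Convolution details.** Valid (no-padding) convolutions and pooling,
  Glorot-uniform initialization, Adam \(\beta_1 = 0.9, \beta_2 = 0.999,
  \epsilon = 10^{-8}\). Internally the encoder runs in single precision
  with channel-major feature maps; the second convolution uses the
  shift-GEMM formulation and bias+ReLU are folded into the pooling pass
  (exact, since max and ReLU commute with a per-channel bias). One master
  seed fans out to initialization, pair sampling and batch shuffling, so
  runs are bit-reproducible on a given BLAS.
- **Summary conventions.** Fold std is the sample (n-1) standard
  deviation; AUC is the midrank statistic; the bootstrap CI is the
  percentile interval of resampled means.
- **Determinism (RQA).** `rqaMetrics()` follows the standard definition:
  the fraction of off-main-diagonal recurrent points lying on diagonal
  runs of length at least `l_min` (default 2). On a fully recurrent
  \(4\times4\) block this gives 10/12, because the two corner points sit
  on length-1 diagonals. These metrics are diagnostics; the pipeline
  consumes the full image.

## The synthetic-data generator

Real clinical corpora of this kind are access-restricted, so the package
ships a generator (`generateCorpus()`) that emits two-class corpora of
valid CHAT files with controllable fluency contrasts. Each transcript
alternates interviewer prompts with participant utterances sampled from a
kitchen-scene vocabulary; per-word filler insertion (`&-uh`/`&-um`),
immediate repetition, pause marks `(.)` and early utterance truncation
(`+...`) are Bernoulli events with per-class rates:

| | filler | repetition | pause | fragment | words/utterance |
|---|---|---|---|---|---|
| control | 0.02 | 0.01 | 0.05 | 0.05 | 8–15 |
| impaired | 0.15 | 0.10 | 0.20 | 0.25 | 3–8 |

Utterance counts default to 8–14 for both classes. The rates were chosen
once to create a detectable but not trivial contrast of the kind the
method targets; a `mild` profile pair with a narrower gap is provided for
monotonicity checks. Consecutive draws never repeat a word, so immediate
repetition is produced only by the repetition mechanism and the rates
stay interpretable. Transcripts are dealt round-robin to participants
(60+60 transcripts over 40+40 participants by default), so some
participants contribute several transcripts and grouped cross-validation
is genuinely exercised.

What the generator does *not* emulate: real lexical and syntactic
structure, topic drift, interviewer back-channel variety, demographic
covariates (age/gender/MMSE columns are placeholders), or the
label-noise and heterogeneity of clinical data. A pipeline that separates
these synthetic classes demonstrates that the machinery — encoding,
recurrence geometry, metric learning, leakage-safe evaluation — works
end to end; it does not certify clinical performance on real corpora.

## Numerical and protocol notes

- Image resampling is implemented as sparse row/column weight matrices;
  area weights are exact rectangle overlaps, so binary plots map into
  \([0,1]\) by convexity and an all-zero plot maps to an all-zero image.
- The classifier grid is scored by inner 3-fold, participant-grouped CV
  on the training fold only; vocabulary and idf weights of the TF-IDF
  baseline are likewise fit per training fold, so no term statistics leak
  from test documents.
- Fold assignment shuffles participants within class and deals them
  round-robin, keeping per-fold class proportions within one participant
  of the global ratio; a runtime assertion verifies the train/test
  participant sets are disjoint in every fold.
- Problem sizes used in the shipped tests: the end-to-end check runs the
  default 120-transcript corpus with 480 pairs per fold and 10 epochs —
  enough for the contrastive geometry to form while keeping a full
  grouped 5-fold run (plus its permutation null) comfortably inside a
  desk-scale compute budget. The bootstrap uses the full B = 10,000.
- Reported real-data headline numbers (mean AUC around 0.95 for the
  character-level pipeline on a clinical corpus) are not reproducible
  here: the source corpus is access-restricted. The package instead
  verifies every desk-scale quantity (fold-statistic arithmetic,
  bootstrap bounds) and validates the pipeline by property-based tests.

## Known limitations

- Single-threaded CPU training only; no GPU path, no data augmentation,
  no pretrained backbones (all deliberate non-goals).
- The alphabet is monolingual Latin-script; phoneme and byte-pair
  encodings are out of scope.
- Only laminarity-free RQA diagnostics (recurrence rate, determinism,
  longest diagonal) are provided; the embedding pipeline itself uses the
  full image.
- Transcript-level scores are not calibrated probabilities; no clinical
  operating point is implied.
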
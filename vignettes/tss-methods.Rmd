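---
title: "Transcription start site prediction: datasets, kernels, cascades and sequence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcription start site prediction: datasets, kernels, cascades and sequence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsspredict)
```

## The problem

The transcription start site (TSS) is the base in genomic DNA where
transcription of an mRNA begins. Locating it means locating the core
promoter, so TSS identification is a central step in understanding
transcriptional regulation. Framed as machine learning, it is a binary
classification problem over fixed-length DNA windows: does this window have a
TSS at its anchor position or not?

`tsspredict` implements the full experimental pipeline for this problem:

1. building labeled window datasets from a genome plus transcript annotation,
   with semi-synthetic negative instances and chromosome-holdout splits;
2. string and numeric kernels (weighted-degree, RBF) with support vector
   machines trained by a cascade scheme;
3. five sequence neural architectures (CNN, LSTM, BLSTM and the two hybrids)
   with a shared training protocol;
4. an imbalance-aware metric suite and harnesses for the class-ratio,
   training-fraction and cross-species experiment designs.

## Dataset construction

### Window geometry

Each instance is a window around an anchor base. The anchor and the two
following bases (in transcript orientation) are treated as a codon;
`upstream_flank` bases before the codon and `downstream_flank` bases after it
are concatenated. The defaults — 700 upstream, 300 downstream — give
`700 + 3 + 300 = 1003`-base windows, whose one-hot encoding has
`4 * 1003 = 4012` features.

Coordinates are 1-based inclusive, the Ensembl convention. On the plus
strand the window covers reference positions `[tss - 700, tss + 302]`; on the
minus strand it covers `[tss - 302, tss + 700]` and is reverse-complemented,
so windows are always reported 5'→3' on the transcript's strand. Strand
orientation matters: a TSS signal is directional, and flank sequences from
annotation exports are strand-aware.

### Positives, negatives, and the class ratio

One positive window is anchored on each annotated TSS. Negative instances
cannot be observed directly, so they are generated semi-synthetically:
for each transcript, anchor positions are sampled uniformly without
replacement from the transcript's genomic span, excluding exact TSS
coordinates (an optional exclusion radius widens this), and excluding
positions whose window would leave the chromosome. The default is 10
negatives per positive, the ratio that works well for this class of genomic
classifier; `undersample_majority()` implements the 1:1 arm of the ratio
experiment, and the test partition is never resampled — the 1:10 ratio
approximates what real data look like.

Windows containing a base outside `{A, C, G, T}` cannot be one-hot encoded;
they are dropped and counted in the dataset's provenance rather than
imputed.

### Chromosome-holdout splits

Random instance-level splits leak positional information between partitions
(nearby windows share sequence). Partitions are therefore defined by whole
chromosomes: by default chromosome 16 is validation and chromosomes 1, 3,
13, 19 and 21 are test, with everything else training — the split used for
the human genome. Because partitions are fixed, classical cross-validation
does not apply; variability is estimated by five seeded repetitions
(`repeat_with_seeds()`): networks re-initialize, cascades re-randomize their
level-0 split.

## Kernels

The weighted-degree (WD) string kernel scores two equal-length sequences by
their positionally matching k-mers up to length $d$:

$$K(s_i, s_j) = \sum_{k=1}^{d} \beta_k \sum_{l=1}^{L-k+1}
  \mathbb{I}\left(u_{k,l}(s_i) = u_{k,l}(s_j)\right), \qquad
  \beta_k = 2\,\frac{d-k+1}{d(d+1)},$$

where $u_{k,l}(s)$ is the k-mer of $s$ starting at position $l$. The weights
decrease linearly in $k$ and sum to one. This is the positional
(shift-free) variant; no mismatch or shift extension is implemented, and no
gram normalization is applied. The default $d = 10$ balances accuracy
against the quadratic cost of the gram matrix.

The implementation maps bases to small integers once per sequence list, and
evaluates each pair with a run-length trick: a maximal run of $r$
consecutive matching positions contributes
$\sum_{k=1}^{\min(r,d)} \beta_k (r-k+1)$, a quantity precomputed per run
length, so a pair costs one vector comparison plus one run-length encoding.
A transparent brute-force implementation (`wd_kernel_naive()`) is retained
as the reference oracle, and the gram builder is block-decomposable with
bit-identical results regardless of the partition.

The RBF kernel $K(x, x') = \exp(-\gamma\,\lVert x-x'\rVert^2)$ operates on
flattened one-hot vectors and provides the numeric-kernel comparison point.

## Cascade SVM

A full SVM on a precomputed string-kernel gram is the pipeline's bottleneck;
the cascade scheme makes it tractable. Training data are split into
`n_subsets` (a power of two) random class-stratified subsets; one SVM is
fit per subset and only its support vectors survive; adjacent
support-vector sets are merged pairwise up a binary tree until a single SVM
remains. The final support set is then fed back into every level-0 subset
and the whole pass repeats. Convergence — which the cascade literature
leaves loosely specified — is declared when the global support-index set is
identical between consecutive passes, with a cap of `max_global_passes`
(default 5). Stratifying the level-0 split matters at 1:10 imbalance:
unstratified subsets can lose the minority class entirely.

Each node is a standard soft-margin C-SVC solved by `kernlab::ksvm` on the
precomputed kernel block (solver tolerance `1e-3`, no class weighting; both
recorded in the serialized model header). The full training gram is
computed once and nodes index into it, so no kernel value is recomputed
within a pass. The resulting model stores support indices into the original
training set, signed dual coefficients bounded by $C$, and the bias; the
decision function is $f(x) = \sum_s \alpha_s K(x_s, x) + b$ with the label
threshold at zero. SVM decision values are not probabilities; for
cross-entropy evaluation a Platt-style sigmoid is calibrated on the
validation split, and probabilities are clipped to
$[10^{-15}, 1-10^{-15}]$ before the logarithm — which is why miscalibrated
SVMs show large but finite cross-entropy values.

## Neural architectures and training protocol

Five architectures operate on the one-hot `(length × 4)` encoding:

| name | layers |
|---|---|
| `cnn` | 3 × [conv1d(32 filters, width 5, stride 1) → maxpool(4)] → dense 1024/512/128 (each + 20% dropout) → sigmoid unit |
| `lstm` | LSTM(128) → dense(64) → 50% dropout → sigmoid unit |
| `blstm` | bidirectional LSTM(128 per direction) → dense(64) → 50% dropout → sigmoid unit |
| `cnn_lstm` | conv1d(64, width 3) → maxpool(3) → 25% dropout → LSTM(64) → 80% dropout → sigmoid unit |
| `cnn_blstm` | as above with a bidirectional LSTM(64 per direction) |

Design points the architecture descriptions leave open, resolved here:
convolutions use no padding ("valid") with pooling stride equal to pool
size; hidden activations are rectified linear; recurrent layers return only
their final state; "bidirectional layer of 128 units" is read as 128 units
per direction with concatenated outputs, the common convention.

All models share one protocol: batch size 32, learning rate 0.001, Adam,
binary cross-entropy loss, at most 100 epochs with early stopping after 10
epochs without validation-loss improvement and restoration of the
best-validation weights. Class imbalance is deliberately *not* reweighted
in the loss; imbalance is handled through the data ratios only.

The training engine is implemented in the package itself — batched
forward/backward passes for every layer kind, with backpropagation through
time for the recurrent layers and orthogonal per-gate recurrent
initialization (Glorot elsewhere, forget-gate bias 1). The test suite
verifies all analytic gradients against central finite differences on every
architecture. Training is seeded end to end: weight initialization, batch
shuffling and dropout masks all derive from the config seed, so runs are
reproducible exactly.

## Metrics

Accuracy, precision, recall (= sensitivity), specificity and F1 derive from
the confusion matrix at a 0.5 probability threshold. Zero-denominator cases
return 0 flagged as undefined rather than erroring — degenerate classifiers
on imbalanced data do hit these cases. Binary cross-entropy uses the
natural logarithm with probabilities clipped at $10^{-15}$. AUC-ROC is
computed by the midrank (Mann–Whitney) formula — the probability that a
random positive outscores a random negative, ties counting one half — which
equals the trapezoidal area under the ROC curve and is invariant under
strictly monotone score transforms; the suite checks it against exhaustive
pair counting.

## The synthetic fixture: what it emulates and what it does not

`generate_fixture()` produces a genome and annotation with a planted,
learnable TSS signal so the whole pipeline runs with no downloads: i.i.d.
background bases at a configurable GC content, transcripts placed in
disjoint slots with random strands, and a consensus motif written at each
TSS codon position on the transcript's strand, each base corrupted with
probability `motif_noise` (per-position consensus retention is therefore
$1 - \mathrm{noise} + \mathrm{noise}/4$). Defaults: 10-base motif
`TATAAAGGCC`, 5% noise, GC 0.41.

The fixture does **not** emulate exon/intron structure, CpG islands,
isoform-level TSS clustering, ambiguity codes, or the correlated background
composition of real genomes. Passing the desk-scale checks therefore shows
that the implementations are correct and that the pipeline can recover a
planted signal — not that the fixture numbers transfer to full-genome
performance, which requires the real data and long training.

### Desk-scale problem sizes

The learnability checks run on deliberately small study conditions chosen
once for desk-scale work: 10 chromosomes of 20 kb, 100 transcripts,
**43-base windows** (upstream 30, downstream 10), 1:10 negatives — about
660 training, 220 validation and 220 test instances. The short window is a
problem-size choice with a methodological reason: a plain LSTM must
backpropagate through the whole window to credit a motif, and with only
~60 positive examples the credit assignment over 1000 steps does not
converge in any reasonable desk budget, while convolutional models (which
detect the motif locally) are length-insensitive. At 43 bases every model
family learns the planted signal well within a few minutes of CPU time.
On these conditions the LSTM and the WD-kernel cascade SVM both exceed
validation AUC 0.9, a model trained on one fixture species transfers to a
second species sharing the motif (AUC ≥ 0.8 without retraining), and
transfers at chance level to a species without the shared signal.

A design point worth recording: the no-shared-signal control cannot plant a
*different fixed* motif. A positionally trained model responds to any fixed
foreign motif deterministically — zero positional overlap makes it an
anti-motif (AUC far below 0.5), partial overlap a weak positive signal — so
the null species instead plants no consistent motif at all
(`motif_noise = 1` redraws every planted base uniformly), making its TSS
neighborhoods exchangeable with background.

## Numerical choices and degenerate inputs

* One-hot alphabet order A, C, G, T; lowercase input is uppercased.
* Gram PSD checks use a $-10^{-8}$ eigenvalue tolerance.
* Negative sampling with fewer eligible positions than requested returns
  all of them with a warning, not an error; zero eligible positions return
  an empty set with a warning.
* `read_biomart_export()` drops and counts rows with null fields, accepts
  `1/-1` or `+/-` strand encodings, and ignores unmapped columns.
* Ties in grid search resolve toward smaller C, then smaller d or gamma.
* Fraction subsets are per-class permutations keyed by seed only, so
  subsets are nested across fractions under a fixed seed.

## Known limitations

* The WD kernel has no shift/mismatch tolerance and no normalization —
  deliberate, to match the printed formula, but it makes the kernel
  strictly positional.
* The cascade equals a full SVM only in easy (near-separable) regimes; in
  general it is an approximation, which is the accepted trade-off for
  tractability.
* The neural engine is CPU-bound base R; it is sized for desk-scale
  experiments, not full-genome training.
* SMOTE-style oversampling is accepted only through an external oversampler
  hook; it is an off-the-shelf technique and not implemented internally.
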
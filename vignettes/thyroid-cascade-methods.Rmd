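---
title: "Methods: a coarse-to-fine cascade for thyroid-nodule ultrasound classification"
author: "ThyroCascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a coarse-to-fine cascade for thyroid-nodule ultrasound classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThyroCascade)
```

## The problem and the model

Ultrasound is the standard first-line imaging modality for thyroid nodules.
A clinical frame contains a dark border (with small bright annotation
artifacts) around a bright, speckled band showing the thyroid itself.
Radiologists grade nodules on the 7-category TI-RADS scale; categories
{1, 2, 3} are grouped as *benign* and {4a, 4b, 4c, 5} as *malign*, which is
the binary target this package predicts.

The pipeline is a two-stage cascade:

1. **Preprocessing.** The frame is binarized with Otsu's threshold, the
   largest bright connected component is kept (the thyroid band; annotation
   blobs are far smaller), and its tight bounding box is cropped.
2. **Coarse frequency screening.** The crop is resized to a fixed square
   grid, transformed with the 2-D FFT, and scored by the power ratio
   `Score = Ps / P`, where `Ps` sums the centered power spectrum inside a
   circle around the DC bin and `P` sums the whole spectrum. Scores below a
   calibrated `thLow` are decided benign, above `thHigh` malign; everything
   in between is *ambiguous* and deferred. Malign nodules — round
   structures with calcification — shift spectral mass, so the two classes
   separate on this single scalar for the easy cases.
3. **Fine CNN ensemble.** Ambiguous crops are resized to the network input
   side, scaled to [0, 1], replicated to three channels, and scored by two
   convolutional heads. Each head ends in the fixed sequence global average
   pooling → batch normalization → dropout → dense layer with two softmax
   outputs; every score in the package is the probability of the *benign*
   class (benign ≡ 1). The two probabilities are fused by the MIN, MAX or
   SUM rule (SUM is the arithmetic mean; MAX is the default, the
   best-performing rule), and a fused score strictly greater than a
   calibrated threshold is decided benign.

Training uses the class-weighted binary cross-entropy
`wBCE = -w0·y·log(p) - w1·(1-y)·log(1-p)` with natural logarithms and
defaults `(w0, w1) = (0.7, 0.3)`: the larger weight goes to the benign term
because benign is the minority class in typical thyroid datasets, which
reduces the bias an unweighted loss develops toward the majority class.
The default optimizer settings are Adam, 30 epochs, batch size 32, learning
rate 1e-4, stop at end of epochs.

## Evaluation protocol

Malign is the positive class: sensitivity = TP/(TP+FN) is the malign
detection rate, specificity = TN/(TN+FP) the benign detection rate, and
accuracy = (TP+TN)/N. Metrics are per image. Cross-validation is at the
*patient* level: patients of each class are shuffled (seeded) and dealt
round-robin into k folds, so per-class patient counts differ by at most one
and no patient contributes images to both training and test. Per fold, the
coarse thresholds, the two heads, and the fused decision threshold are all
fitted on the k−1 training folds only. The reported result is the
unweighted mean of the per-fold metrics, not a pooled confusion table. No
validation split is held out; training stops at end of epochs.

A metric whose class is absent from the ground truth is reported as `NA`
(undefined), never silently as 0.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `radiusFraction` | 0.1 | circle radius as fraction of half the smaller spectrum dimension |
| `includeDC` | TRUE | DC bin counts in both `Ps` and `P` |
| `spectrumSide` | 256 px | square grid the ROI is resized to before the FFT |
| `purity` | 0.95 | per-side purity required of coarse-decided training samples |
| `minAreaFraction` | 0.05 | smallest admissible ROI area relative to the frame |
| `connectivity` | 8 | pixel connectivity for component labeling |
| `rule` | max | fusion rule |
| loss weights | (0.7, 0.3) | benign (minority) and malign term weights |
| epochs / batch / lr | 30 / 32 / 1e-4 | reference training protocol |
| `dropout` | 0.5 | head dropout rate (no rate is prescribed by the tables) |

Rationale for the frequency-stage choices: no circle radius is prescribed,
so a small low-frequency disk (0.1) is the default and the calibration CLI
emits the per-sample score table so users can sweep it. The ROI is resized
to a fixed 256×256 grid before the FFT because the number of bins inside a
fixed-fraction circle otherwise varies with ROI aspect ratio, making scores
incomparable across images. No windowing is applied — the method uses a
plain FFT. Scores exactly equal to a threshold route to *ambiguous*: the
safer direction, deferring to the stronger classifier.

## Numerical and design choices

- **Otsu's threshold** is computed on the 256-bin histogram; the returned
  threshold is an integer, ties in the between-class variance resolve to the
  smallest maximizer, and the foreground is *strictly greater than* the
  threshold, compared on binned intensities so fractional values within one
  bin never straddle it. A constant image carries a `degenerate` flag and
  the ROI extractor raises rather than silently passing.
- **Connected components** default to 8-connectivity (speckle fragments
  4-connected regions); a size tie keeps the component whose first pixel
  comes first in row-major order. Components are labeled via the pixel
  adjacency graph (igraph).
- **Bounding boxes** are 0-based, half-open on both axes. No padding is
  applied around the detected box.
- **Resizing** is bilinear with the half-pixel-center convention
  (EBImage's filter).
- **Losses** clip probabilities at 1e-7 before the logarithm; the natural
  log is used (the minimizer is unaffected by the base).
- **Coarse calibration.** `thLow` is the largest cut whose strictly-below
  tail is ≥ purity benign, `thHigh` the smallest cut whose strictly-above
  tail is ≥ purity malign; a side with no satisfying cut collapses to
  ∓∞ and never fires. On well-separated data the two independently fitted
  sides can cross; the calibrator then collapses both onto the single cut
  that maximizes the number of decided training samples subject to both
  purity constraints, preserving the invariant `thLow ≤ thHigh`.
- **Decision-threshold calibration.** Training accuracy is piecewise
  constant in the threshold; the calibrator enumerates the constant
  intervals in [0, 1] (including the degenerate top cut t = 1), keeps the
  optimal ones, returns 0.5 when 0.5 is itself optimal, and otherwise the
  midpoint of the widest optimal interval, ties toward 0.5.
- **Equality at the fused threshold** is decided malign: the decision rule
  is strictly "larger than".
- **Batch normalization at inference** uses statistics re-estimated exactly
  over the training set with the final weights; running averages lag badly
  on short training schedules.
- **Determinism.** Every stochastic step (weight init, shuffling, dropout,
  phantom synthesis, fold assignment) derives from an explicit seed and
  restores the caller's RNG state, so identical configuration and data give
  bitwise-identical results.

## The network heads

The two reference backbones are represented as exact layer-by-layer
enumerations with full parameter accounting: every convolution (with biases
where the canonical architecture defines them — ResNet50 yes, Inception-v3
no) and every batch-normalization vector (four per feature; Inception-v3's
batch norms omit the scale vector). Under this convention the enumerations
reproduce the published totals exactly — 23,587,712 ResNet50 and 21,802,784
Inception-v3 backbone parameters at 224×224×3, with 8,192 batch-norm and
4,098 dense head parameters — and the backbone output grids are 7×7×2048
and 5×5×2048 respectively. These heads carry no weights: no deep-learning
framework (and no pretrained weight source) is part of this package's
dependency set, and fine-tuning a 23M-parameter backbone is not a
desk-scale operation.

All training-dependent behaviour runs on the `tiny` backbone: three
3×3-convolution + ReLU + 2×2-max-pool blocks (8, 16, 32 channels) feeding
the same head, implemented natively in R (im2col convolutions as matrix
products, Adam, full backpropagation — verified against numerical
gradients). The dense head layer is zero-initialized, so an untrained head
emits exactly 0.5 and fine-tuning starts from an unbiased decision.

## What the phantom generator emulates — and what it does not

`generatePhantom` reproduces the structural features the cascade relies on:
a dark border with a few small bright artifact blobs (annotation marks), a
central bright thyroid band under multiplicative log-normal speckle (the
standard first-order ultrasound speckle approximation), a smooth
illumination gradient, and — for malign phantoms — one round bright,
homogeneous nodule (damped internal speckle) carrying bright calcification
specks. The nodule is a large low-frequency structure, so malign phantoms
concentrate more spectral power near DC and score *higher* on the frequency
ratio; contrast scales linearly with `classSeparation`, and at separation 0
the malign additions vanish so the two classes are statistically
indistinguishable. Frames default to 560×360, the size of the reference
public dataset's exports.

The generator does **not** simulate acoustic physics: no point-spread
function, no attenuation or shadowing, no anatomical variability, no
TI-RADS sub-features (margins, echogenicity grades, shape). Passing tests
therefore demonstrate that the pipeline's machinery is correct and that its
statistical contracts hold under the assumed image structure — not that the
method achieves any particular accuracy on clinical data.

## Study sizes used by the packaged experiments

Chosen as the package's desk-scale study conditions:

- **Cross-validated recovery**: 50 patients per class, one image each, at
  the default phantom conditions (560×360 frames, full separation), 5
  folds, `tiny` heads trained 10 epochs at learning rate 0.01 (the compact
  backbone trains from scratch, so it uses a larger step than the
  fine-tuning default). With well-separated phantoms the coarse stage
  decides nearly all test images and mean accuracy exceeds 0.9.
- **Loss-weighting study** (`imbalanceStudy`): 10 benign vs 90 malign
  training phantoms at reduced frame size (240×160) and moderate separation
  0.5 — chosen so the classes genuinely overlap and a trained classifier
  must trade sensitivity against specificity; 40+40 balanced test phantoms;
  gaps averaged over a small training-seed set. Raw network predictions at
  threshold 0.5 are evaluated (no coarse stage), isolating the loss
  function as the only moving part.

## Known limitations

- The reference backbones are enumerations, not executable networks;
  training and prediction require the `tiny` backbone.
- The frequency score's physical orientation (malign scoring higher) is
  taken from the cascade's stated decision layout and engineered into the
  generator; on real data where the ordering reverses, the dual-threshold
  calibration still works because both tails are fitted independently.
- Manifests are plain CSV; converters from clinical annotation formats
  (e.g. the reference dataset's XML) are a documented extension point, as
  is any frequency-region shape other than the circle.
- Multiple images per patient are independent rows sharing a `patient_id`;
  metrics are per-image. Patient-level aggregation would be a deliberate,
  flagged choice.
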
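---
title: "Methods: cascade frequency-domain and CNN classification of thyroid ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascade frequency-domain and CNN classification of thyroid ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Ultrasound is the first-line imaging modality for thyroid nodules, and
computer-aided systems aim to separate benign from malignant (here: *malign*)
nodules without biopsy. A clinically useful observation drives this package:
malign nodules frequently carry microcalcifications — small, bright,
high-contrast deposits — whose fine, often directionally organized structure
shifts image energy toward high spatial frequencies, while benign tissue shows
a smoother, near-isotropic power spectrum. That contrast is visible in the 2-D
power spectrum long before a classifier is involved, which suggests a cheap
frequency-domain test that can resolve the easy cases and reserve the
expensive convolutional network for the genuinely ambiguous ones.

The pipeline is a cascade with an abstention state:

1. **Tissue extraction.** The raw frame contains a dark background (near 0),
   bright annotation artifacts (near 255) and the speckled tissue fan. The
   frame is binarized at the Otsu level, morphologically closed, labeled with
   8-connectivity, and the largest connected component is kept; its tight
   bounding box, with off-mask pixels zeroed, is the tissue crop all later
   stages consume.
2. **Frequency-domain pre-classification.** The crop is resampled to a fixed
   square grid, mean-subtracted, Fourier-transformed, center-shifted and
   squared in magnitude. The score is the ratio of power inside a parametric
   spectral mask to total power, `fftscore = P_i / P`, both sums excluding the
   zero-frequency bin. Two calibrated thresholds `TH_LOW <= TH_HIGH` map the
   (oriented) score to one of three states: *benign*, *benign-malign*
   (undecided), or *malign*. Confident states are final.
3. **CNN resolution.** Undecided crops go to a convolutional classifier: a
   residual-network backbone whose classification top is replaced by global
   average pooling over the final `(m, n, k)` feature map, batch normalization
   over the `k` pooled features, dropout, and a 2-unit softmax output. The
   head adds `k * 4` batch-norm parameters and `2 * (k + 1)` output
   parameters.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `closing_radius` | 5 px | disc radius closing the Otsu foreground; speckle fragments the tissue blob and without closing "largest object" is ill-defined |
| `min_area_fraction` | 0.05 | largest component below this fraction of the frame is "no tissue found" |
| `side` | 256 | spectral grid; fixes mask geometry across variable crop sizes |
| mask grid | radii {8, 16, 24, 32, 48}, bar half-widths {1, 2, 4, 8} | tuning candidates spanning low-to-mid frequencies for the five shapes (circle, horizontal, vertical, plus, circle-plus) |
| `alpha` | 0–0.05 | calibration quantile; at 0 the first stage makes no error on its own calibration data |
| `dropout_rate` | 0.5 | head dropout |
| learning rate | 1e-4 → 1e-5 | geometric per-epoch decay over 10 epochs |
| `batch_size` | 8 | Adam minibatch size |

Choices the underlying method description leaves open, decided here once:

* **Foreground convention** is intensity at or above the Otsu level, because
  the ultrasound background sits near zero.
* **Ties** in Otsu's between-class variance break toward the smallest level;
  ties in component area break toward the component whose centroid is nearest
  the frame center (the thyroid occupies the central fan); ties in mask
  tuning break toward fewer selected bins (the more parsimonious mask).
* **RGB reduction** uses the ITU-R BT.601 luminance weights, the common
  default for 8-bit clinical frame grabs.
* **DC handling.** The image is mean-subtracted before the transform and the
  zero-frequency bin is excluded from both the numerator and denominator of
  the score. This makes `fftscore` a pure texture statistic: invariant to
  overall echogenicity shifts and to linear intensity scaling (both are
  verified as properties in the test suite). With R's unnormalized DFT the
  total spectral power equals `side^2` times the summed squared deviation of
  the resampled image (Parseval), which the suite also checks.
* **Score orientation** (whether malign cases score high or low) is learned
  at calibration rather than hard-coded. Which side the malign class falls on
  depends on the mask geometry — a DC-centered circle concentrates the smooth
  benign energy — so the model stores a direction and orients scores before
  thresholding. `TH_LOW` is the `alpha`-quantile of oriented malign training
  scores, `TH_HIGH` the `(1 - alpha)`-quantile of benign ones; when the
  classes separate the two thresholds collapse to their midpoint and the
  undecided band is empty. Quantiles use linear interpolation between order
  statistics (type 7), deterministic and standard.
* **Boundary convention.** A score exactly at either threshold is undecided,
  and a CNN probability of exactly 0.5 is called malign — the conservative
  direction for a screening tool.
* **Spectra of constant crops** carry no texture signal; they are routed to
  the CNN rather than raising an error, so every valid tissue crop receives a
  label.
* **Whether to transform the full frame or the crop** is open in the source
  description; the crop is used, since the mask geometry is only comparable
  across images when the tissue occupies the whole transformed field.

## The network, its accounting, and training

The backbone families follow the standard 18/34-layer (two-conv basic block)
and 50-layer (1x1–3x3–1x1 bottleneck) residual designs, with biased
convolutions and batch-norm layers carrying scale, shift and running
statistics. Under that accounting — every tensor counted, including the
non-trainable running statistics — the 50-layer convolutional backbone counts
exactly 23,587,712 parameters, which the acceptance suite asserts. The same
accounting yields 11,190,912 for the 18-layer and 21,310,208 for the 34-layer
backbone; published figures for those two (11,186,889 and 21,302,473) do not
match any standard tensor accounting we could reconstruct, so the package
documents its own counts rather than forcing a match.

No deep-learning framework is required: convolution is im2col plus a BLAS
matrix product, and every layer implements an analytic backward pass
(verified against central-difference numerical gradients in the suite).
Training minimizes 2-class cross-entropy with Adam; the learning rate decays
each epoch by the constant factor `(end_lr / initial_lr)^(1/(n_epochs - 1))`,
interpreting a "continuous" reduction as the simplest rule that meets both
printed endpoints (1e-4 at epoch 1, 1e-5 at epoch 10). The output layer is
zero-initialized: at these small learning rates a randomly initialized
boundary would dominate the 10-epoch budget, whereas from zero the first Adam
steps set the boundary along the class-mean direction, and training accuracy
on separable fixtures reaches 100% within a few epochs. Dropout is inactive
and batch-norm uses running statistics at prediction time. The recorded
per-epoch loss/accuracy come from an end-of-epoch pass over the whole
training set in inference mode, free of dropout and minibatch noise.
Pretrained-weight transfer is supported as a load-if-provided hook
(`load_network_weights()`); random initialization is the default so the
package builds with no external downloads. The `tiny_test` backbone — four
stride-2 convolution blocks ending in 32 channels — exists so the full
train/predict path runs on one CPU in minutes; it is not a clinical
architecture.

## What the phantom generator emulates

The generator reproduces the gross radiological structure that the pipeline
exploits, with every quantity recorded as ground truth:

* near-zero background with mild sensor noise;
* annotation glyphs near 255 placed in the periphery, kept at least 20 px
  clear of the tissue box so that no plausible morphological closing can
  bridge them into the tissue component;
* a large rectangular tissue region filled with multiplicative
  gamma-distributed speckle (shape 4, mean 1 — the standard fully-developed
  speckle surrogate), always the largest bright connected component;
* a hypoechoic nodule disc (intensity multiplied by 0.55) present in **both**
  classes, since benign nodules exist too; and
* for malign phantoms only, punctate bright calcification discs on a
  jittered axis-aligned lattice inside the nodule. The lattice spacing
  injects directional high-frequency energy, which is what makes the
  bar-family masks discriminative by construction; the label is *derived*
  from the calcification count, so a malign spec with the spots removed
  renders its benign twin bit-for-bit.

Default effect sizes (speckle mean 120, calcification intensity 245, twelve
spots of radius 2 at spacing 10 inside a radius-60 nodule) were chosen so the
two classes separate in the frequency domain with a score ROC area above 0.9
— the regime in which the cascade's division of labor is observable. What
passing phantom tests show is that the implementation is faithful to the
method; they do not show clinical performance. Real ultrasound has
depth-dependent attenuation, fan-shaped geometry, operator-dependent gain,
heterogeneous parenchyma, and nodules whose calcifications are neither
lattice-like nor guaranteed — none of which the phantom models. Published
accuracies on clinical collections are therefore not reproduced here.

## Evaluation protocol

Malign is the positive class throughout: sensitivity `TP/(TP+FN)`,
specificity `TN/(TN+FP)`, accuracy `(TP+TN)/m`. A class absent from a fold
yields an undefined (`NA`) metric, not an error. One source text passage
states the identities backwards ("TN + FP = n" after defining n as
positives); the standard identities are implemented. Splitting is by patient
— all images of a patient stay together — with two modes: `repeated_random`
draws a fixed-size test set per fold independently (the default, matching a
benchmark protocol of 11 benign + 50 malign test patients drawn anew per
fold, which a strict partition of 52 benign patients could not provide), and
`stratified_partition` gives disjoint near-equal folds. Whether evaluation
should pool images or patients is unspecified in the source description, so
decisions are per image by default and a per-patient aggregation (malign if
any image malign) is available in both `classify_cohort()` and
`cross_validate()`.

## Problem sizes and numerical notes

The shipped tests and the acceptance script run the full cascade on a
20-benign + 20-malign phantom cohort with two cross-validation folds
(5 + 5 test patients per fold) and the `tiny_test` backbone — sizes chosen so
a complete desk run finishes in minutes on one CPU while still exercising
every stage end to end; the shared test fixture uses 10 + 10. Degenerate
inputs are handled explicitly: constant images are rejected by Otsu
binarization with a clear error, constant crops defer to the CNN, empty
foregrounds and undersized components raise "no tissue found", and
calcification layouts that cannot fit their nodule are rejected at spec
construction. Known limitations: no DICOM ingestion, no BMP decoding, no
nodule-level detection, no data augmentation, and no attempt to reproduce
clinical-collection accuracies.
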
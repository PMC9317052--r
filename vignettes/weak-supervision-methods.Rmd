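---
title: "Ellipse-box weak supervision for tumor segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ellipse-box weak supervision for tumor segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `ellipseg`, the choices
that were genuinely open when the package was designed, and what its tests
do and do not demonstrate.

## The weak-supervision model

The package targets binary glioma segmentation (all tumor sub-regions —
necrotic and non-enhancing core, edema, enhancing tumor — merged into one
class by `binarize_label()`). Exact per-pixel masks are assumed to exist for
only a small number of patients; every other training image carries only a
rough localization, from which a cheap surrogate label is built:

* a **moment-matching ellipse** is fitted to the localization
  (`fit_ellipse()`): the ellipse with the region's centroid and second
  central moments, i.e. semi-axes `2 * sqrt(eigenvalues)` of the pixel
  covariance and the principal-axis orientation. Because a manually drawn
  ellipse surrounds the tumor rather than matching its moments, the fitted
  ellipse is dilated by 1.05 (`initial_ellipse()`). The 1.05 is a package
  default for emulation, not an empirical constant — nothing in the
  protocol pins down how generously a human draws.
* shrinking the initial ellipse by `p1 = 0.9` gives the **foreground**
  region: for a tumor that is itself roughly elliptical, the shrunken
  ellipse sits strictly inside it, so foreground pixels are tumor with high
  purity (the phantom study measures ~0.92 at the default irregularity).
* enlarging it by `p2 = 1.2` gives the **background** boundary: everything
  outside is normal tissue with purity ~1.
* the annulus between the two ellipses is labelled **ignore**. The protocol
  defines positives from the small ellipse's interior and negatives from
  the large ellipse's exterior and says nothing about the band between;
  excluding it from the loss is the only reading consistent with both
  purity claims, and `trimap_loss()` guarantees ignore pixels contribute
  exactly zero loss and zero gradient.

Both scale factors are tunable per trimap (`make_trimap(initial, shape, p1,
p2)`); `p1 >= p2` is rejected because the annulus would be empty or
inverted.

## Network

`build_multistream()` constructs one U-Net stream per modality. Per stream:
five downstream blocks of double 3×3 convolution + ReLU with widths
(32, 64, 128, 256, 512), batch norm after each double-conv pair, 2×2
max-pooling after blocks 1–4, and dropout (rate 0.10) at the end of the
downstream path; four upstream blocks of 2×2 stride-2 transposed
convolution, skip concatenation with the matching downstream block, batch
norm (absent in the first upstream block), and double 3×3 convolution with
widths (256, 128, 64, 32). Streams never share weights; their final
32-channel maps are concatenated and a 1×1 convolution + per-pixel softmax
classifies tumor vs non-tumor.

Three readings of the architecture's tabular description were genuinely open:

* the transposed convolutions are printed with a constant 128 channels in
  every upstream block, which is incompatible with symmetric skip
  concatenation; the package defaults to the symmetric reading (transpose
  channels match the skip partner) and keeps the literal variant behind
  `literal_transpose_128 = TRUE`.
* the stride column is read as the pooling stride; 3×3 convolutions run at
  stride 1, since stride-2 convolutions combined with 2×2 pooling would
  collapse a 176-pixel input below one pixel in four blocks.
* "simple feature-level fusion" is implemented as channel concatenation
  followed by a 1×1 convolution — the simplest operator matching the
  phrase. No batch norm before the classifier.

All convolutions use 'same' padding (176 is incompatible with valid-padding
U-Net arithmetic), so input sizes must only be divisible by 16. A
reduced-width configuration (`reduced_spec()`: 64-pixel input, widths
8–128) is first-class and used throughout the test suite; parameter count
scales approximately quadratically in the width multiplier, which a test
verifies.

The engine itself — im2col/GEMM convolutions, transposed convolutions,
max-pooling in C++; batch norm, dropout, softmax, losses and Adagrad in R —
is part of the package and is validated against naive R reference
implementations and finite-difference gradient checks down to relative
error 1e-4 (typically 1e-9).

## Training protocol

`train_two_round()` implements the two-round schedule: the coarse round
minimizes the weighted trimap cross-entropy on the weakly labelled patients
(defaults: 70 epochs), the refinement round minimizes per-pixel weighted
cross-entropy against true masks on the annotated patients (150 epochs),
with all layers trainable in both rounds and the Adagrad state reset
between rounds (the rounds optimize different objectives on different label
sets). Defaults follow the protocol's standard settings: Adagrad, learning rate 1e-3,
batch 16, L2 1e-3 on convolution kernels, flip/shear(≤0.2°)/scale(±10%)
augmentation applied identically to image and label (nearest-neighbour for
labels).

Class weights follow the inverse pixel-frequency rule `w_fg / w_bg =
mean(BG pixels) / mean(FG pixels)`, normalized to `w_bg = 1`, ignore pixels
excluded; the protocol specifies only that weights derive empirically from
this ratio, so the exact rule is a declared default. Two
consequences are worth knowing:

* the weighting is deliberately recall-oriented. On phantoms it drives
  tumor sensitivity to ~100% at the cost of dilating the prediction into
  the unsupervised annulus (over-segmentation); the refinement round then
  pulls the boundary back to the true edge. This is visible in the
  package's own experiments and is why the weak-only invariant test uses
  balanced weights: it isolates the geometric question (does ellipse-box
  supervision pin the boundary?) from the imbalance-handling knob.
* round 2 also recomputes weights from mask frequencies, keeping the
  imbalance treatment consistent across rounds; `round2_class_weights =
  FALSE` disables this.

`transfer_refine()` covers the small-dataset regime: a model pre-trained on
a larger cohort initializes the network, and refinement updates **all**
layers — not just the top ones — because domain mismatch (different
scanners, acquisition settings, here: different phantom contrast vectors)
perturbs low-level features too. A test asserts that every weight tensor
moves and that test dice on the new domain improves.
`train_fully_supervised()` trains the identical architecture on fully
annotated data and is the comparison baseline for `degradation_report()`.

## Data handling

Slices are standardized per channel to zero mean and unit (population)
variance and resampled to a square (default 176; bilinear for images,
nearest for labels). Normalization is per slice, not per dataset — it
requires no global pass and matches the stated per-image normalization.
Splits are strictly patient-separated (`split_patients()`), with counts
`round(fraction * n)` for train and validation and the remainder as test;
the protocol's cohort arithmetic reproduces exactly (285 → 171/57/57 at 60/20/20 and
75 → 15/60 at 20/80). Slice extraction from 3-D scans takes, per view, the
slice with maximal tumor area as center and adds neighbours by the
alternating rule center, +step, −step, +2·step, … (out-of-range offsets
skipped); the standard setting (3 slices per view, step 5) yields nine
slices per scan, and the 18-slice small-dataset setting follows from the
same rule, whose exact offset pattern was unstated and is a declared
convention here. Which patients are annotated is a deterministic first-k
choice after a seeded shuffle.

## The phantom generator

`generate_phantoms()` emulates the data regime the protocol addresses:
co-registered 2–4 channel 2-D slices; one star-convex tumor per patient
(an ellipse base with a smoothed per-angle radial perturbation — harmonics
2–5, amplitude `0.15 × irregularity`), consistent across a patient's slices
up to ±2-pixel jitter; a smooth low-frequency background field (clipped to
[0.4, 0.6]) shared across modalities; signed per-modality tumor contrast
(defaults ±0.3–0.4, emulating bright-on-T1ce / dark-on-T1 behaviour); and
independent Gaussian noise (default σ 0.06). Defaults were chosen once as
a realistic desk-scale rendition of high-contrast glioma slices: tumor area
2–8% of the image, irregularity 1 (clearly non-elliptical boundaries, ~15%
RMS radial deviation), noise an order of magnitude below contrast. The
star-convex construction guarantees a meaningful gap between any ellipse
approximation and the true mask — exactly the regime the trimap is supposed
to survive — and the truth mask marks the tumor pixels before noise, so
separability is exact at σ = 0.

What the phantoms do **not** emulate: anatomy (no tissue classes, no
skull), bias fields, registration error, multi-focal lesions, or
modality-specific noise statistics. Passing the end-to-end study therefore
shows that the pipeline's machinery — trimap construction, masked weighted
loss, two-round schedule, patient-separated evaluation — behaves as
designed on separable data; it does not certify clinical performance.

## Numerical choices

Rasterization uses the closed interior (pixel center satisfies the ellipse
inequality), making every geometric operation deterministic and
resolution-independent. Coordinates are 1-based (row, col) pixel centers —
the R convention — with orientation measured counter-clockwise from the
column axis in `[-π/2, π/2)`. Batch norm uses ε = 1e-5 and running-moment
momentum 0.9 (batch statistics during training, running statistics at
inference); Adagrad uses ε = 1e-7; kernels are He-normal initialized;
softmax ties at exactly 0.5 resolve to background. The L2 penalty enters
the gradient as `2λW` on convolution kernels only (not biases or batch-norm
parameters). All randomness — phantom sampling, splits, annotation choice,
shuffling, augmentation, dropout, initialization — derives from integer
seeds through a deterministic hash, so identical configurations reproduce
bit-identical runs; training is single-threaded deterministic arithmetic.

## Problem sizes

The bundled study (`phantom_study_config()`) uses 30 two-modality patients
at 64×64 with the reduced-width network: 24 training patients (20 weak, 4
annotated — the <20 annotated budget) and 6 test patients, 8 coarse and 12
refinement epochs at learning rate 0.02 and batch 8 — sizes chosen so a
full three-repetition comparison runs in minutes on one CPU while leaving
the protocol's structure intact. Unit tests use a further reduced 32-pixel
configuration. The full-scale defaults (176-pixel input, widths 32–512,
70/150 epochs, learning rate 1e-3, batch 16) are the package defaults for
`network_spec()` and `train_config()`.

## Known limitations

Single lesion per image (multi-lesion localizations collapse to the
largest component before ellipse fitting); 2-D slices only (no 3-D
convolutions); binary segmentation only; no early stopping (fixed epoch
budgets; best-on-validation checkpointing is available but off by
default); the degradation report's standard deviation combines the two
protocols' across-run σ in quadrature, which treats them as independent
and is flagged as an approximation; and the CPU engine, while exact, is
not meant for full-resolution multi-epoch clinical training.
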
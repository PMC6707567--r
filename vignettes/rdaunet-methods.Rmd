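---
title: "Methods: architecture, training objective and synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: architecture, training objective and synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Lesion segmentation in breast ultrasound (B-mode, "BUS") images is hard for
the classic U-Net because BUS images combine strong multiplicative speckle,
low lesion/background contrast and weak boundaries. The RDAU-NET
architecture implemented here modifies U-Net in three places:

1. **Residual units** replace plain convolution stacks. Each unit computes
   `y = relu(F(x) + W_s x)` with `F` the sequence conv(3×3, stride S) — BN —
   ReLU — conv(3×3) — BN, and `W_s` a 1×1 projection used whenever channel
   count or resolution changes (identity otherwise). The derivative
   `∂y/∂x = 1 + ∂F/∂x` keeps gradients alive in deep stacks; the package
   verifies this identity by finite differences in its test suite. The
   encoder has six units (stride 1, then five stride-2 units, so the side
   halves five times: 128 → 4); the decoder has five stride-1 units with
   channel schedule 512, 256, 128, 64, 32. The encoder schedule for units
   2–6 is 64, 128, 256, 512, 512; the unit-1 width is not fixed by the
   source architecture and defaults to 32 here, mirroring the decoder's
   final width.
2. **A dilated-convolution bridge** at the bottleneck: six parallel 3×3
   convolutions with dilation rates 1, 2, 4, 8, 16, 32, each followed by
   ReLU; their outputs are summed and upsampled ×2 into the decoder. The
   receptive-field bookkeeping used for reporting is
   `side = (K+1)(r−1) + K`, giving 3, 7, 15, 31, 63, 127 at K = 3. Note
   this is deliberately the architecture's own accounting: the usual
   dilated-kernel span is `K + (K−1)(r−1)` (5, not 7, at K = 3, r = 2). The
   convolution arithmetic itself samples at offsets `i·r` as usual; only
   the reporting function uses the larger formula.
3. **Attention gates** on the skip connections:
   `α = σ(W_k (W_int relu(W_h h + W_g g + b) + b_int) + b_k)` with all four
   kernel banks 1×1, `h` the encoder skip and `g` the decoder-side signal
   at the same resolution (the gate never interpolates; the wiring
   guarantees equal sizes because `g` is taken after the decoder-side
   upsample). `α` has a single channel, broadcast over the channels of
   `h` — the formulation of the attention-U-Net lineage. The two input
   projections share one bias vector, as the gate equation is written.

The head is a 1×1 convolution plus sigmoid giving a per-pixel lesion
probability. Ablation variants are build flags: RAU (bridge replaced by a
single plain 3×3 conv block + the same ×2 upsample), DAU (residual units
replaced by conv-BN-ReLU ×2 stacks without shortcuts), RDU (gates removed,
raw skip concatenation). The source material names these variants but never
defines them; these semantics — remove exactly one ingredient, keep
everything else — are this package's design choice, and make the four
variants directly comparable in parameter count (RDAU − RDU equals exactly
the summed attention-gate parameters).

## Numerical choices

* **Padding**: all convolutions use zero "same" padding (output side
  `ceil(side/stride)`), required for the bridge to operate on 4×4 maps at
  dilation 32 and to preserve sizes as the block diagrams show. With even
  input sides and stride 2 the extra padding pixel goes bottom/right.
* **Downsampling** is by stride-2 convolution on the first conv of each
  encoder unit (the block diagram's `S`), not pooling.
* **Batch norm**: ε = 1e-5, running statistics by exponential moving
  average with momentum 0.9, warmed up as a cumulative average over the
  first ~10 steps so that evaluation-mode forward passes are sane in short
  runs. Placement is conv→BN→ReLU→conv→BN, add, ReLU after the addition
  (whether an activation follows the addition is unstated in the source;
  ReLU-after-add is standard residual practice).
* **Upsampling**: nearest-neighbour ×2, isolated in one function so
  bilinear or transposed convolution are drop-in replacements.
* **Initialisation**: He-normal, seeded (two builds from one config are
  bit-identical). The head kernel is scaled by 1e-3 — near-neutral so the
  sigmoid starts at ~0.5 where the Dice gradient is informative, but
  non-zero so gradient reaches the decoder (an exactly-zero head blocks all
  upstream gradient, which we observed as a hard training stall).
* **Loss**: soft Dice, `1 − (2Σpg + s)/(Σp + Σg + s)` with smoothing
  `s = 1` so empty-vs-empty is defined; mean over the images of a batch.
* **Optimiser**: Adam; package default learning rate 1e-4 (recorded in
  every run config). Model selection keeps the best-validation-Dice
  parameters.
* **Binarisation**: probability 0.5 (unstated in the source; recorded in
  the run config).
* **Zero-denominator conventions**: precision, sensitivity, specificity
  and F1 return 0 when their denominator is empty.

Reported metrics: soft Dice loss and (binarised) Dice averaged per image;
accuracy, sensitivity, specificity, F1 and precision from pooled pixel
confusion counts; M-IOU as the mean over images of the lesion-class IOU
(the alternative reading — averaging lesion and background IOU per image —
is not used); AUC as pixel-pooled trapezoidal ROC-AUC, with PR-AUC
reported alongside, since whether the headline AUC is ROC or PR, pooled or
averaged, is unstated in the source material. The CSV column order is
Loss, Acc, DC, Sen, Sp, F1, Pc, M-IOU, AUC.

## Paired augmentation

Four affine transforms applied identically to image and mask: vertical
shift, horizontal shift, shear, and a left-right mirror ("horizontal
flipping" is read as mirroring across the vertical axis; configurable).
Magnitudes are drawn uniformly per sample from ±10% of the side (shifts)
and ±10° (shear) under a stated seed — the source gives the transform list
and the 730 → 2919 expansion but not the magnitudes. Images are resampled
bilinearly, masks by nearest neighbour (so they stay strictly binary), and
exposed borders are filled with 0 (echo-free black). Each original yields
exactly four transformed copies, so `m` inputs give `5m` samples; the
literal 4-per-image scheme gives 2,920 new samples from 730 originals
versus the printed 2,919 — an off-by-one in the source that this package
does not attempt to reproduce.

## The synthetic phantom generator

`generate_phantom()` emulates exactly the B-mode properties the
segmentation task depends on:

* a **hypoechoic lesion**: a rotated ellipse (semi-axes 12–28% and 10–22%
  of the side) whose radius is modulated by seeded low-frequency angular
  harmonics (orders 2–5) scaled by `boundary_irregularity` — 0 for
  benign-like (smooth) contours, 0.15–0.35 for malignant-like (spiculated)
  ones;
* **low contrast**: background mean 0.45–0.65, lesion darker by 0.15–0.30;
* **multiplicative speckle**: each pixel multiplied by the mean of
  `speckle_looks` squared standard-normal draws — the standard mean-one
  multi-look (gamma-type) speckle model; datasets draw 1–4 looks;
* **system blur**: Gaussian, σ ≈ 1 px, applied after speckle;
* the mask is the exact pre-noise lesion support.

What the generator does *not* emulate: physically propagated wavefronts
(no RF/PSF simulation), posterior acoustic shadowing and enhancement (an
optional darkened-column artifact was considered and left out of the
default stated world), multi-lesion scenes, heterogeneous tissue texture,
and — importantly — the domain shift between the three clinical sources of
the original datasets. A green synthetic benchmark therefore establishes
that the architecture, gradients, optimiser and metrics work end to end
and can learn a speckled low-contrast segmentation task; it does not
establish clinical-grade performance, which requires the real BUS data and
GPU-scale training.

## The desk-scale benchmark

The package's stand-in for the real-data experiment trains RDAU-NET on 500
phantoms (50 validation, 100 test, all side 64, batch 32, 30 epochs) and
requires test Dice ≥ 0.80 plus a strictly positive improvement over the
first epoch. Two desk-scale adaptations, both chosen a priori and recorded
here:

* **channel widths scaled by 1/8** (encoder 4, 8, 16, 32, 64, 64; decoder
  64, 32, 16, 8, 4). The full-width network costs ~7 GFLOP per image for
  forward+backward; 15,000 image-passes exceed 10^14 FLOP, i.e. hours on
  one CPU, whereas the reduced width finishes in minutes. A narrower
  network makes the Dice bound harder, not easier, to reach.
* **benchmark learning rate 1e-3** (the conventional Adam default),
  appropriate for a small network and ~470 optimiser steps; the package
  default stays 1e-4.

Early training passes through a plateau in which the Dice gradient shifts
all probabilities uniformly before spatial features break the symmetry;
with very few optimiser steps (a handful of epochs on tens of images) some
seeds are still on that plateau, which is why the quick smoke tests pin a
seed. The 30-epoch benchmark is well past it.

## Known limitations

* PNG (and text PGM) are the supported image formats; no BMP/TIFF reader
  exists in the dependency set.
* The engine is CPU-only and double-precision; it is written for
  correctness (every block is oracle-tested, every backward pass
  finite-difference-tested) and moderate scale, not for GPU-class
  throughput.
* `receptive_field_side()` reports the architecture's own accounting (see
  above), which overstates the conventional dilated-kernel span.
* Augmented samples are generated in memory; the manifest records
  transform and magnitude, not a hash of pixel content.
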
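---
title: "Lightweight adversarial modality transfer: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight adversarial modality transfer: models, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`stedgan` implements unpaired and paired image-to-image translation for
fluorescence microscopy: mapping diffraction-limited confocal images of
thin, cilium-like structures to their super-resolved STED or deconvolved
STED (dSTED) counterparts, with a systematic ladder of generator sizes
ranging from a conventional 41.8-million-parameter U-Net down to a
fixed-channel variant with roughly nine thousand parameters. This vignette
explains the models, the design decisions that were genuinely open, the
synthetic phantom generator used for all testing, and what the test suite
does and does not establish about real microscope data.

## The two frameworks

Both frameworks train a U-Net generator against a PatchGAN discriminator
that scores overlapping local patches rather than whole images.

**Pix2Pix** (paired): the generator $G$ minimizes an adversarial term plus
an L1 reconstruction term against the registered target,

$$\mathcal{L}_{\mathrm{Pix2Pix}}(G, D) = \mathcal{L}_{\mathrm{GAN}}(G, D)
  + \lambda \, \mathbb{E}_{x,y}\,\lVert y - G(x) \rVert_1 ,$$

with the conditional discriminator seeing the (source, candidate) pair.
The log-form adversarial objective is optimized in its non-saturating form
for the generator.

**CycleGAN** (unpaired): two generator–discriminator pairs with
cycle-consistency and identity terms,

$$\mathcal{L} = \mathcal{L}_{\mathrm{GAN}}(G, D_Y)
 + \mathcal{L}_{\mathrm{GAN}}(F, D_X)
 + \lambda_{\mathrm{cyc}}\big(\mathbb{E}_x|F(G(x)) - x|_1
   + \mathbb{E}_y|G(F(y)) - y|_1\big)
 + \lambda_{\mathrm{id}}\big(\mathbb{E}_y|G(y) - y|_1
   + \mathbb{E}_x|F(x) - x|_1\big).$$

Nothing on the CycleGAN path consults pairing; shuffled target collections
train identically.

**Weights and optimizer.** The published hyperparameter table is not
available, so the package exposes every knob in `loss_weights()` and
`train_config()` with the values that are canonical for these frameworks:
$\lambda = 100$, $\lambda_{\mathrm{cyc}} = 10$, $\lambda_{\mathrm{id}} = 5$,
Adam with learning rate $2\times10^{-4}$ and betas $(0.5, 0.999)$, batch
size 4, 200 epochs with the learning rate decaying linearly to zero from
epoch 100, checkpoints every 5 epochs (the final epoch is checkpointed
regardless). Pix2Pix defaults to the log (non-saturating) GAN loss per its
objective; CycleGAN defaults to least squares, its original practice; both
are selectable. The CycleGAN discriminators draw fakes from a seeded
50-image pool.

## The nine-model registry

Two channel policies are implemented:

* **doubling** — channels double at each down-sampling stage, capped at
  eight times the base width; Models 1–4 and 6 use base widths 64, 32, 16,
  8 and 4 with seven resolution levels, 4×4 kernels, stride 2 and
  concatenated skips. Model 1 reaches the 512-channel bottleneck.
* **fixed** — every level uses the same channel count; Models 5, 7, 8 and
  9 use widths 64, 32, 16 and 8.

```{r}
library(stedgan)
model_registry()
```

**Bias-free convolutions.** Convolutions carry no bias terms and instance
normalization no affine parameters. This is a coherent convention when
normalization follows most convolutions, and it is the convention under
which the doubling family's counts land exactly on the published ladder at
printed precision (41.8, 10.45, 2.61, 0.65, 0.16 million): with per-channel
biases the width-32 and width-16 variants round to 10.46 and 2.62 instead.

**Model 6's base width.** The prose description of the doubling ladder
("down to 8 channels") conflicts with the figure caption (base 4,
bottleneck 32). Only base 4 satisfies the quartic scaling of the ladder
(0.16 ≈ 41.8/256), so the registry uses base 4.

**Fixed-family calibration.** The published ladder fixes the fixed-family
widths and their parameter counts (0.53, 0.13, 0.035, 0.009 million) but
not the depth, kernel size or skip mode. `calibrate_fixed_family()` scores
every (depth ∈ 3..7, kernel ∈ {3, 4}, skip ∈ {concat, add}) triple by the
summed relative error of its analytic counts against that ladder. The
optimum — four levels, 4×4 kernels, concatenated skips — reproduces the
width-64 and width-32 counts exactly (527,360 → 0.53 M; 132,608 → 0.13 M)
and the width-8 count at the published rounding (8,576 → 9 k). No triple
in the space reproduces all four: the width-16 variant lands at 33,536
parameters (0.034 M) against the published 0.035 M. We freeze the optimum
and report the residual rather than stretch the architecture family with
ad-hoc extra layers to chase the last digit; the exact published layer
structure of the small fixed models remains an open question.

**Other architectural choices.** Instance normalization is applied to all
but the outermost and bottleneck convolutions (normalizing a 1×1 bottleneck
map is degenerate). Dropout (p = 0.5) sits in the innermost three decoder
blocks, is active only during training, and is disabled at inference. The
final activation is tanh, so generators operate on the symmetric range
[-1, 1]; `to_net_range()`/`from_net_range()` convert to and from the [0, 1]
metric range. The PatchGAN discriminator (widths 64, 128, 256, 512 by
default, 4×4 kernels) is shared by all nine generator variants — the
published table lists generator parameters only, implying a fixed
discriminator.

## The CNN core

No deep-learning framework is used: convolutions, transposed convolutions,
instance normalization and Adam are implemented in the package
(Rcpp/RcppArmadillo, im2col + GEMM with a per-layer column cache), and
every backward pass is validated against central finite differences in the
test suite. Training is CPU-only and deterministic given a seed: all
randomness — phantom geometry, weight initialization, shuffling, dropout,
the image pool — flows through R's RNG via `seed_all()`.

## The phantom generator

`generate_phantom()` emulates the statistical structure of co-registered
acquisitions of fluorescently labeled primary cilia:

* **Geometry** — one to three smooth random curvilinear tracks (natural
  splines through random control points) rasterized at constant linear
  density with a Gaussian cross-section of 2.5 px FWHM. Thin elongated
  structures are the point: cross-profiles through two nearby membranes
  show two peaks under a narrow PSF and a single merged peak under a wide
  one, the key qualitative behavior the translation task must reproduce.
* **Optics** — each modality is a Gaussian PSF blur (reflective boundary,
  unit-sum kernel): σ = 4 px (confocal), 1 px (STED), 0.7 px (dSTED),
  enforcing the resolution ordering dSTED < STED < confocal. dSTED is
  emulated as a narrower-PSF, lower-noise render; iterative maximum-
  likelihood deconvolution itself is out of scope.
* **Noise** — scaled Poisson shot noise (photon scales 100 / 300 / 800 for
  confocal / STED / dSTED, so confocal is noisiest and dSTED cleanest)
  plus Gaussian read noise (σ = 0.01). These magnitudes are free
  parameters chosen once to separate the quality classes under the
  non-reference metrics; published descriptions of sub-optimal acquisition
  conditions are qualitative only.
* **Degradation** — low-quality variants apply scan-order photobleaching
  (`exp(-rate * row)`, rate 0.01/line), random labeling gaps (20% of the
  support), and extra Gaussian noise (σ = 0.05).

What the phantoms do **not** emulate: vectorial/aberrated PSFs, depletion-
power effects, 3-D structure, autofluorescence background, detector
artifacts, or the morphological diversity of real biological samples. A
passing suite therefore demonstrates that the machinery is correct and
that the training dynamics behave as published at desk scale — not that
any particular fidelity will be reached on real microscope data.

## Preprocessing

The pipeline mirrors standard ImageJ practice: a saturated-quantile
contrast stretch (default saturation 0.35%, ImageJ's default, applied as
fraction/2 per tail), Gaussian smoothing (σ = 1 px) + Otsu threshold +
largest connected component for segmentation, a bounding-box crop with an
8 px margin applied identically to both images of a pair, zero padding to
128 × 128 with centered placement, and per-image min–max normalization.
Two deliberate policies: crops larger than the pad size raise an error
rather than silently rescale (rescaling distorts morphology and pixel
size), and augmentation — a uniform draw from the 8-element dihedral group
applied identically to source and target — happens per training iteration,
never pre-expanded on disk. Whether normalization is per image or per
dataset is not standardized in this setting; we normalize per image and flag the
choice here.

## Metrics

* **SSIM** — 11 × 11 Gaussian window (σ = 1.5), K1 = 0.01, K2 = 0.03,
  sample-covariance normalization, mean over the fully-windowed region;
  verified to 10⁻⁶ against an independent reference implementation.
* **PSNR** — `10 log10(range² / MSE)`, `+Inf` for identical images.
* **Normalized PSNR** — the reference workflow plots a "normalized PSNR" in [0, 1]
  with the self-comparison at (1.0, 1.0) but never defines it; we
  implement `min(psnr / cap, 1)` with a configurable 40 dB cap and the
  identity mapped to 1 by convention.
* **FRC** — per-ring normalized cross-correlation of the two Fourier
  transforms over 1-px rings up to Nyquist, Hann apodization on by
  default. High-frequency disagreement is `1 - mean(FRC)` over the upper
  half of Nyquist (no canonical band exists; upper half is
  our default). FRC resolution uses the fixed 1/7 threshold with linear
  interpolation at the crossing and a light 3-ring running mean; curves
  that never cross are Nyquist-limited (2 px, flagged). One subtlety: the
  per-ring normalized correlation is invariant to linear filtering of
  noiseless images (each ring normalizes the filter gain away), so
  resolution orderings across PSF widths are measured on shot-noise
  renders against the ground truth, where the blur determines how quickly
  signal falls below the noise floor.
* **Non-reference metrics** — SNR as (foreground mean − background mean) /
  background sd under an Otsu split; edge preservation as the variance of
  the Laplacian on the [0, 255] scale (Tenengrad gradient energy
  available); deviation maps as pixel-wise |generated − observed| with the
  mean as an anomaly score. The source names these metrics without
  formulas; ours are standard reconstructions, and only orderings — never
  absolute values — are asserted anywhere.

## Evaluation protocol

`kfold_split()` partitions image pairs into 5 folds (sizes within one,
seeded, no stratification); every pair appears in exactly one validation
fold. Per-image metrics are pooled across folds before statistics — the
source does not say whether it pooled or averaged per fold, and pooling is
recorded in the output metadata. `rm_anova()` computes the one-way
within-subjects F statistic (images as subjects, model as the
within-factor) directly from mean squares, cross-checked against base R's
`aov(y ~ model + Error(subject/model))`; no sphericity correction is
applied by default (Greenhouse–Geisser
could be added). Pairwise comparisons are two-sided paired t-tests on
per-image differences with the Holm step-down adjustment, cross-checked
against `p.adjust`. Degenerate designs are reported, not errored: identical
columns give F = 0, p = 1; a perfectly consistent offset gives F = Inf,
p → 0.

## Desk-scale problem sizes

The test suite exercises full training at sizes a single CPU handles
comfortably while preserving the study's structure: the headline check
trains a Model 9 CycleGAN on 64 synthetic 128 × 128 pairs for 30 epochs
and requires the held-out mean SSIM of the translated images (16 pairs) to
exceed the confocal baseline, and the cycle loss to decrease from the
first to the last epoch. For these desk-scale runs the discriminators use
reduced widths (16, 32) — the ladder fixes the generator, not the
discriminator, and a full 70×70 PatchGAN is disproportionate against an
8,576-parameter generator on phantoms. Statistical calibration uses 1,000
null simulations of 100 subjects × 5 models. Smoke tests of both training
loops run at 32 × 32 with 4-channel generators.

## Known limitations

* The Gaussian-PSF, Poisson-plus-Gaussian forward model is deliberately
  simple; it supports orderings and calibration checks, not quantitative
  PSF fitting.
* Model 8's parameter count (0.034 M) cannot be brought to the published
  0.035 M within the calibrated architecture family (see above).
* Training is CPU-bound; the parameter-rich Models 1–3 build and count
  correctly but are not meant to be trained in this implementation at
  realistic dataset sizes.
* Inference-time and checkpoint-storage benchmarks are serialization- and
  hardware-dependent and are intentionally not reproduced.
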
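# stedgan

Lightweight adversarial modality transfer for fluorescence microscopy, in R.

Confocal microscopy is diffraction-limited (~200 nm); STED (stimulated
emission depletion) microscopy resolves far finer structure but demands
high depletion power, careful alignment and photobleaching-prone
acquisition. `stedgan` implements the computational alternative: training
image-to-image translation networks that map confocal images of thin,
cilium-like structures to STED-like or deconvolved-STED-like renderings —
and asks how small the generator can be. It is written for microscopists
and methods researchers who want a fully inspectable, CPU-only, seeded
reimplementation of this pipeline with no deep-learning framework
dependency.

The package provides:

* **Two adversarial frameworks.** Pix2Pix (paired; adversarial + λ·L1,
  conditional PatchGAN) and CycleGAN (unpaired; two generator/discriminator
  pairs with cycle-consistency and identity terms,
  L = L_GAN(G, D_Y) + L_GAN(F, D_X) + λ_cyc·L_cyc + λ_id·L_id).
* **A nine-model generator registry.** The conventional channel-doubling
  U-Net at base widths 64/32/16/8/4 (Models 1–4, 6; Model 1 has a
  512-channel bottleneck and 41.8 M parameters) and a fixed-channel
  lightweight U-Net at widths 64/32/16/8 (Models 5, 7–9; Model 9 has ~9 k
  parameters). The CNN core — convolutions, transposed convolutions,
  instance norm, Adam, backprop — is implemented in Rcpp/RcppArmadillo and
  gradient-checked in the test suite.
* **A synthetic phantom generator** producing co-registered
  confocal/STED/dSTED/low-quality image sets of spline-based curvilinear
  emitters with Gaussian-PSF optics and Poisson + Gaussian noise, so the
  whole system trains and tests without any external data.
* **Preprocessing** (saturated-quantile contrast stretch, Otsu
  segmentation and cropping, zero padding to 128×128, dihedral
  augmentation), **metrics** (SSIM, PSNR, normalized PSNR, Fourier ring
  correlation with 1/7-threshold resolution and high-frequency
  disagreement, line profiles with Pearson correlation, non-reference SNR,
  edge preservation, deviation maps), and an **evaluation harness**
  (5-fold cross-validation, repeated-measures ANOVA, Holm-corrected
  pairwise tests) with broom-style `tidy()`/`glance()` and `autoplot()`
  methods.

## Worked example

Generate phantoms, train the smallest CycleGAN, and score it against the
confocal baseline:

```r
library(stedgan)

ds  <- generate_dataset(64, phantom_config(seed = 11))       # train pairs
val <- generate_dataset(16, phantom_config(seed = 1211))$samples

fit <- train_cyclegan(ds, gen_spec = registry_spec(9),
                      disc_spec = discriminator_spec(widths = c(16L, 32L)),
                      config = train_config(epochs = 30, batch_size = 4,
                                            seed = 7))

mean(sapply(val, function(p)
  ssim(translate(fit$G, to_net_range(p$source))$pixels, p$target$pixels)))
#> [1] 0.583
mean(sapply(val, function(p) ssim(p$source$pixels, p$target$pixels)))
#> [1] 0.371
fit$history$cycle[c(1, 30)]
#> [1] 1.498 0.160
```

The translated images are structurally closer to the STED targets (mean
held-out SSIM 0.58) than the confocal inputs are (0.37), and the
cycle-consistency loss falls by an order of magnitude over 30 epochs —
the unpaired framework's headline behavior, reproduced at desk scale with
an 8,576-parameter generator on one CPU core in roughly a quarter of an
hour.

The model ladder itself:

```r
model_registry()
#>   model policy   base_width depth kernel_size skip_mode n_params params_m
#> 1     1 doubling         64     7           4 concat    41815040   41.8
#> 2     2 doubling         32     7           4 concat    10454528   10.45
#> 3     3 doubling         16     7           4 concat     2614016    2.61
#> 4     4 doubling          8     7           4 concat      653696    0.65
#> 5     5 fixed            64     4           4 concat      527360    0.53
#> 6     6 doubling          4     7           4 concat      163520    0.16
#> 7     7 fixed            32     4           4 concat      132608    0.13
#> 8     8 fixed            16     4           4 concat       33536    0.034
#> 9     9 fixed             8     4           4 concat        8576    0.009
```

A thin command-line surface wraps the same functions
(`inst/cli/stedgan.R`): `simulate`, `preprocess`, `train`, `translate`,
`evaluate`, `compare`, `count-params`.

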
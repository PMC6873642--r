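# fibreSR

Unsupervised super-resolution for fibre-bundle endomicroscopy (pCLE), in R.

Probe-based confocal laser endomicroscopy images tissue through a bundle of
optical fibres: each fibre samples one tissue point, and the scanner
reconstructs a pixel image from the per-fibre signal vector by
Delaunay-based linear interpolation over the fibre centres. The result is
oversampled but blurry, and no true high-resolution ground truth exists —
only imperfect references estimated by video registration — so supervised
super-resolution is not an option.

fibreSR implements an unsupervised adversarial framework with a *physical*
cycle consistency. A fully convolutional generator `SR` maps a reconstructed
LR frame to a same-size super-resolved frame; a discriminator `DS` compares
its outputs against patches from an arbitrary HR target domain. The
generator minimizes

```
loss_t = l_Vec + l_Adv + l_Reg
l_Vec  = (1/N_F) Σ_i [ V(I_LR)_i − V̂(SR(I_LR))_i ]²     (cycle consistency)
l_Adv  = −log DS(SR(I_LR))                               (non-saturating adversarial)
l_Reg  = mean_y[row-mean diff]² + mean_x[col-mean diff]² (histogram regularizer)
```

where `V(I_LR)` is the normalized per-fibre acquisition vector of the input
and `V̂(·)` is the *Voronoi vectorization* of the output — per-cell averaging
over the bundle's Voronoi partition, min–max normalization, zero-padding to
the fixed length `N_F`. The cycle block is a fixed physical operator, not a
learned inverse network: the super-resolved image must re-acquire, through
the bundle geometry, to the same fibre signals it came from. The
discriminator maximizes `log(1 − DS(SR(x))) + log DS(y)`.

The package provides, as testable modules:

- **Acquisition simulator** — jittered hexagonal bundle layouts, per-pixel
  Voronoi maps, cell-averaged fibre signals, additive/multiplicative
  Gaussian signal noise, and Delaunay barycentric reconstruction (the
  geometry kernels are implemented in-package and verified against
  brute-force oracles).
- **Cycle block** — Voronoi vectorization and acquisition vectors in the
  shared normalized, padded form.
- **Losses and training** — the objectives above plus an Adam-based
  alternating training loop over small conv nets (a pure-R engine: im2col +
  BLAS matmul with hand-derived, finite-difference-verified backprop).
- **Synthetic studies** — tissue-like textures, natural-image stand-ins,
  paired/unpaired HR–LR studies with patient/video metadata and
  group-exclusive CS1/CS2 splits.
- **Evaluation** — SSIM, the reference-free global contrast factor (GCF),
  contrast improvements ΔGCF versus the HR reference and the LR input, the
  composite score `Tot_cs = ½[(SSIM−0.6)/0.4 + (ΔGCF_HR+0.5)/1.82]`, report
  aggregation and a paired t-test.

## Worked example

Simulate a 200-fibre acquisition of a synthetic tissue frame, reconstruct
the LR image, and score it against the HR original:

```r
library(fibreSR)

layout <- generateFibreLayout(200, c(96, 96), jitter = 0.3, seed = 1)
hr     <- generateTextureHR(96, seed = 1)
sim    <- simulateLRfromHR(hr, layout, noiseParams(0.02, 0.05, seed = 1))
lr     <- ImageFrame(pmin(pmax(frameData(sim$lr), 0), 1), role = "LR")

evaluateMethod(list(f1 = lr), list(f1 = hr), list(f1 = lr))
#> MetricsReport (untagged): 1 images
#>   ssim_hr  0.69 ± 0.00
#>   dgcf_hr  0.27 ± 0.00
#>   dgcf_lr  0.00 ± 0.00
#>   tot_cs   0.33 ± 0.00
```

Cell averaging and interpolation cost the LR frame structural similarity to
the HR original (SSIM 0.69), while the per-fibre signal noise inflates its
measured global contrast above the clean reference (ΔGCF +0.27 against HR;
0 against itself by construction); the composite score 0.33 weighs both
effects. A training run on such a study (see `?trainAdversarial` and the
vignette's desk-scale protocol) learns a generator whose outputs raise the
composite score of the LR inputs.

A command-line wrapper covers the same pipeline
(`inst/cli/fibresr.R synth | simulate | train | infer | evaluate`), writing
a YAML config snapshot next to every artifact.

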
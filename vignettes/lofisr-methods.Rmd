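---
title: "Methods: k-space degradation, network wiring and training protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-space degradation, network wiring and training protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofisr)
```

## The acquisition model

Low-field MR scanners trade field strength for cost and portability, and the
price is paid in signal-to-noise ratio: images come out noisy and, for a
fixed scan time, at low resolution.  `lofisr` models the resulting
low-resolution image `y` as a *k-space truncation* of the high-resolution
image `x`,

    y = F_LR^{-1} D F_HR x + n,

where `F_HR` is the 2-D Fourier transform on the high-resolution grid
(128×128 by default), `D` keeps only the centred low-frequency block
(64×64), `F_LR^{-1}` inverts the transform on the coarse grid, and `n` is
complex Gaussian noise in k-space.  This follows the MR acquisition process:
scanning for half the time samples half the k-space extent per dimension,
and thermal noise enters per acquired k-space sample.  It is deliberately
*not* the blur-then-decimate model of classical super-resolution.

Conventions are fixed once, package-wide, because every downstream contract
depends on them:

* **Centred, orthonormal transforms.** The DC coefficient sits at 0-based
  index `floor(N/2)`; transforms are unitary, so Parseval holds exactly and
  round-trips are accurate to ~1e-15.
* **Half-open crop window.** `central_crop()` keeps indices
  `[N/2 - n/2, N/2 + n/2)` per dimension — frequencies `-n/2 .. n/2 - 1`,
  the asymmetric Nyquist handling implied by the DC-at-`floor(N/2)`
  convention.
* **Grid-size rescaling.** A factor `sqrt(hw/HW)` is applied after cropping
  (and its inverse after padding) so a noise-free constant image maps to
  the same constant at every resolution.  Without this the intensity scale
  of LR/HR pairs would be arbitrary and PSNR comparisons meaningless.
* **Magnitude output.** The LR image is the complex magnitude of the
  inverse transform (`magnitude_output = TRUE`).  Magnitude is how MR
  images are displayed, and pushing circular complex k-space noise through
  magnitude produces the Rician-like image-domain noise characteristic of
  low-field scans.  The real-part alternative remains available as a
  configuration flag; linearity tests use it, since magnitude is the one
  non-linear step of the operator.
* **Noise parameterisation.** Practical noise levels are relative, so
  `sigma = rho * RMS(|cropped k-space coefficients|)`, with `rho` drawn
  uniformly per image from `noise_rho_range`.  The default range
  `(0.02, 0.20)` spans visually mild to severe degradation of the synthetic
  phantoms; it is a configuration field, not a constant, because real
  acquisitions should be matched by measurement, not assumption.

`zero_fill_sr()` is the classical baseline the network must beat: embed the
measured low-frequency block in a larger zero grid and invert.  For images
whose spectrum already lies inside the retained block (band-limited
images), degrade-then-zero-fill is exact — a property the test suite
exploits as a machine-checkable oracle.

## Synthetic phantoms

`generate_phantom()` replaces an external brain-image database for
development and testing.  Each phantom is an outer "skull" ellipse (always
fully inside the frame) painted with a base intensity, overpainted by 3–8
random inner ellipses, boundary-smoothed (Gaussian, `smooth_sigma = 1`
pixel) and modulated by a low-frequency multiplicative texture
(`texture_amp = 0.1`).  Intensity-level diversity stands in for the
T1/T2/FLAIR contrast variety of a real training set.

What the phantoms emulate: piecewise-smooth anatomy with sharp boundaries,
nested structure, strictly zero background, `[0, 1]` intensities.  What
they do not: tissue-contrast physics, partial-volume effects, anatomical
plausibility, coil or field inhomogeneity.  Passing the end-to-end test
therefore shows the *pipeline* learns to undo this degradation model on
piecewise-smooth images; it does not certify clinical image quality.

`build_dataset()` writes paired `hr/*.npy`, `lr/*.npy` and a
`manifest.yaml` holding every seed and noise level, so any stored LR image
is exactly reproducible from its HR source.  Splits are assigned at the
phantom level; the manifests are the audit trail showing no image leaks
across train/val/test.

### Patch pairing

Training uses 32×32 HR patches with 16×16 LR patches.  LR patches are
*cut from the full degraded LR image* at halved (even) origins — not
produced by degrading HR patches — because degrading a 32×32 patch in its
own k-space is a different operator (periodic boundary, coarser frequency
grid) than the full-image acquisition model, and would leak wrap-around
artifacts into training.  Patch origins are sampled uniformly with
replacement; a consequence worth knowing is that border pixels are covered
by fewer patch placements, so patch statistics reflect a centre-weighted
measure of the image rather than the plain pixel mean.

## Network architecture and the wiring calibration

The network is an SRDenseNet-style dense convolutional network: 8 dense
blocks of 8 convolutional layers (3×3, ReLU), each layer emitting 16
feature maps and receiving the block input concatenated with all preceding
layer outputs, so each block contributes 128 new maps.  Every block's
output is carried by skip connections to a 1×1 bottleneck that reduces the
1024 concatenated maps to 256, followed by a single stride-2 transpose
convolution (upsampling factor 2) and a final 3×3 convolution to one
channel with no activation.  There is no normalization layer anywhere.

That description leaves several wiring choices open: whether an initial
convolution precedes the first block and how wide it is, whether its
features join the bottleneck concatenation, whether inter-block skips also
accumulate into each block's *input*, the transpose-convolution kernel and
width, and bias usage.  All are knobs of `model_config()`, and
`calibrate_wiring()` resolves them by enumerating a knob grid analytically
(the per-layer closed form `k² · c_in · c_out + c_out·biases`) against a
target trainable-parameter count, cross-checking the formula against
introspection of built models.

Against the reference count of 1,910,689 parameters, the grid contains
exactly one match with the bottleneck fixed at 256 maps and the final
kernel at 3×3 as the architecture states:

* initial 3×3 convolution with **65** maps, *not* fed to the bottleneck,
* blocks chained (skips concatenate into the bottleneck only),
* **no biases**,
* transpose convolution with kernel **2**, stride 2, **24** output maps.

Per stage: 585 + 1,623,168 + 262,144 + 24,576 + 216 = 1,910,689.  The
straightforward readings land elsewhere (≈2.08M with a kernel-2 deconv at
256 maps, ≈2.4M with kernel 3, ≈4.7M with cumulative skip inputs), which is
why the calibration is part of the package rather than a one-off note.
These calibrated values are the `model_config()` defaults; every knob can
still be overridden.

Kernel-2 stride-2 transpose convolution is the non-overlapping upsampling
variant (each output pixel is written by exactly one input pixel), which
also avoids checkerboard artifacts.  Weights are He-uniform (fan-in)
initialised, seed-controlled; transpose-convolution fan-in is scaled by
`1/stride²` to account for the scatter overlap pattern.

## The training engine

No deep-learning framework is part of the package's dependency footprint;
the network runs on a compact convolution engine in `src/` written with
RcppArmadillo.  Layers are described as a flat list over a tensor graph
(tensor 0 = input, layer *l* → tensor *l+1*, each layer consuming the
channel-concatenation of arbitrary earlier tensors), which expresses dense
connectivity and skips without special cases.  Convolutions are evaluated
as im2col + BLAS sgemm in single precision, batched so a 20-patch training
step runs as one matrix product per layer; the transpose convolution is the
exact adjoint of a stride-2 convolution and reuses the same geometry.  The
backward pass mirrors the forward pass; at the ReLU kink the subgradient 0
is used, the standard convention.  Gradient correctness is pinned in the
test suite against finite differences on an independent double-precision R
implementation of the same graph.

Single precision is the standard arithmetic for network training; all
degradation, metric and loss computations outside the network remain in
double precision.  The engine contains no RNG and no threading of its own,
so identical seeds give bit-identical runs on the same CPU.

### Optimisation protocol

Adam (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`) at learning rate 1e-3,
batch size 20, minimising MSE between network output and clean HR patches;
an epoch is one pass over the training patches in seeded shuffled order.
After every epoch the validation loss is recorded and the returned model is
the checkpoint with the smallest validation loss, ties to the earliest
epoch — the epoch budget is a cap, not a target.  `l1` and `hfen` losses
are available as alternatives.  HFEN (high-frequency error norm) is defined
as `‖LoG(pred) − LoG(target)‖₂ / ‖LoG(target)‖₂` with a 15×15
Laplacian-of-Gaussian kernel at σ = 1.5 — the standard definition from the
compressed-sensing literature — with the kernel normalised to exact zero
sum so constant offsets contribute nothing; filtering uses edge-inclusive
symmetric padding and the training gradient uses the exact adjoint of that
padded filter.

## Evaluation

PSNR is `10·log10(data_range²/MSE)` with `Inf` as the identical-image
sentinel; SSIM uses a Gaussian window (11×11, σ = 1.5), `K1 = 0.01`,
`K2 = 0.03`, averaged over valid window positions.  `data_range` is pinned
at 1.0 package-wide because every image is normalized to `[0, 1]` by its
own maximum before degradation; the value is echoed into every report since
PSNR is meaningless without it.  Network output is clamped to `[0, 1]` only
at export and before metrics — raw forward output is unconstrained.
`evaluate_sr()` writes per-image rows (`metrics.csv`) and per-method
mean ± sd (`summary.yaml`) for the zero-filling baseline and, when a model
is supplied, the network reconstruction.

## Problem sizes in the test suite

The suite exercises the full pipeline at desk scale, chosen so the whole
run stays comfortable on a single CPU while still being informative:

* operator and metric properties: grids of 8–128, 100-fixture property
  sweeps, brute-force O(N⁴) DFT oracles on grids up to 16×16;
* overfit smoke: a 2-block × 2-layer model fit to 20 patch pairs until the
  training MSE drops below 1e-3 (capped at 2,000 steps);
* end-to-end: 500 phantom pairs (400/50/50 split), the calibrated 1.9M
  parameter model trained for a fixed budget of 2 epochs over 2,000
  patches, evaluated on the 50 held-out pairs.  The expected outcome is
  directional — mean PSNR and SSIM strictly above the zero-filling
  baseline — since absolute reconstruction quality keeps improving with
  training budget far beyond this scale.

## Known limitations

* The phantom generator's realism is geometric, not physical; transfer to
  in-vivo data requires training on real image pairs.
* The noise-level range default is a stand-in for scanner-measured values.
* Whether the original acquisition pipeline took the magnitude or the real
  part after the inverse FFT is not documented anywhere we could anchor on;
  magnitude was chosen for its Rician noise behaviour and display fidelity.
* Non-Cartesian or partial-Fourier sampling, coil combination and any
  scanner physics beyond the truncation-plus-noise model are out of scope.
* Training at full scale (~190,000 patches, dozens of epochs) is a
  GPU-scale undertaking; the package reproduces the procedure and its
  direction of effect, not the absolute metric values of any particular
  trained instance.
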
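---
title: "Restoring low-dosage photoacoustic microscopy images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoring low-dosage photoacoustic microscopy images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mtrdn)
```

## The problem

Optical-resolution photoacoustic microscopy (OR-PAM) images blood vessels
by firing laser pulses at each scan position and recording the
ultrasound generated by optical absorption. Image quality, imaging speed
and laser dosage are locked in a three-way trade-off: faster scanning
requires higher pulse rates, which forces lower per-pulse energy to stay
under the ANSI safety limit, which lowers the signal-to-noise ratio;
sparse (undersampled) scanning reduces the pulse count but costs spatial
resolution. This package implements a learned reconstruction that takes
dual-wavelength (532 and 560 nm) images acquired at a fraction `f` of the
ANSI-limit pulse energy and undersampled `s`-fold per scan axis — a
dosage reduction of `s^2 / f`, e.g. 16-fold at (f = 1/4, s = 2) and
32-fold at (f = 1/2, s = 4) — and restores full-sampling,
full-energy-quality, vessel-enhanced images, from which blood oxygen
saturation (sO2) can be estimated by spectral unmixing.

## The model

The restoration network has three subnetworks, each a residual dense
network (RDN):

* **Subnetwork 1** maps the degraded 532 nm input to its full-sampling,
  full-energy ground truth (denoising + `s`-fold super-resolution).
* **Subnetwork 2** does the same for the 560 nm channel.
* **Subnetwork 3** takes the channel concatenation of the two restored
  outputs (at full resolution, so its own upsampling factor is 1) and
  produces the fused, vessel-enhanced product, supervised by the
  vesselness-filtered 532 nm ground truth.

One RDN comprises two shallow 3×3 feature-extraction convolutions, `D`
residual dense blocks (each `C` densely connected 3×3 convolutions with
ReLU and growth rate `G`, a 1×1 local-feature-fusion convolution back to
`G0` channels, and a local residual connection), global feature fusion
(1×1 then 3×3 convolution over the concatenated block outputs) with a
global residual to the first shallow feature map, sub-pixel
(pixel-shuffle) upsampling when `scale > 1`, and a final 3×3
reconstruction convolution. The network is fully convolutional, so any
input of at least 8×8 pixels obeys the scale contract exactly.

Training minimizes the weighted multisupervised loss

    L = w1 |o1 - g1| + w2 |o2 - g2| + w3 |o3 - g3|

(mean absolute error per branch, weights normalized to sum to one) with
Adam. Because all three weights are positive, gradient reaches every
subnetwork: the fusion branch backpropagates through subnetworks 1 and 2
in addition to their direct supervision — this multisupervision is what
distinguishes the architecture from three independently trained networks.

### Architecture and training defaults, and why

* `D = 4, C = 4, G = 16, G0 = 32` — a small profile whose training fits
  on a single CPU; the full-scale published RDN profile (D = 16, C = 8,
  G = 64) is reachable through the same configuration fields. The exact
  depths used with the original in-vivo data were not published; these
  are the package's own documented defaults.
* `loss_weights = (0.25, 0.25, 0.5)` — the fusion output is the headline
  product, so its branch carries the largest share; the trained weighting
  used originally is unpublished, so this is an exposed default.
* Loss = mean absolute error; nonlinearity = ReLU; upsampling = sub-pixel
  rearrangement. The loss and these operator choices are standard for
  image restoration; the original loss function is not named in print.
* Optimizer Adam, `lr = 1e-3`, no schedule; batch = 2 patch tuples;
  patches of 32×32 low-resolution pixels, stride = patch (the original
  tiling has no stated overlap). Overlap-averaged stitching is available
  because visible seams otherwise appear at tile borders.
* Subnetwork 3 receives only the concatenated outputs of subnetworks 1
  and 2, not the raw inputs — the published description combines "Outputs
  1 and 2" and nothing else.

## The degradation forward model

`apply_energy_scaling` multiplies the image by `f` and adds zero-mean
Gaussian noise of fixed SD (detector-noise-dominated model: the noise
floor does not scale with pulse energy, so SNR is proportional to `f`),
then clips to [0, 1]. `undersample` keeps every `s`-th row and column
(pure decimation, no interpolation): the published patch geometry —
200×200 ground-truth tiles against 100×100 inputs at 2× and 50×50 at 4× —
forces per-axis decimation with no pre-interpolation. The two wavelength
channels get independent noise fields (two physical lasers). The noise SD
of the original in-vivo data is unpublished; `noise_sigma = 0.05` on the
normalized scale is this package's default, chosen to produce the
distinct graininess characteristic of low-pulse-energy acquisitions
while leaving vessels clearly visible.

## The vessel-enhancement target

The third supervision target is the full-sampling 532 nm image filtered
by a multiscale Frangi vesselness operator: per scale, the
scale-normalized (σ²) Gaussian-derivative Hessian is diagonalized per
pixel (|λ1| ≤ |λ2|), and the tubularness response is
`exp(-R_B²/2β²)(1-exp(-S²/2c²))` with `R_B = λ1/λ2`,
`S = √(λ1²+λ2²)`, zeroed where `λ2 > 0` (vessels are bright); the final
response is the maximum over scales, min-max normalized. Defaults:
scales σ ∈ {1, 2, 3, 4} px, β = 0.5, and `c = "auto"` (half the maximum
`S` per scale) — the parameterization used to build the original
enhancement target is in an unavailable reference, so these are
documented, overridable choices. The filter is the enhancement operator
itself; no attempt is made to reproduce the vascular distortions its
original large-scale implementation introduces beyond what the filter
inherently does.

Numerical notes: Gaussian-derivative kernels are sampled on a
±⌈3.5σ⌉ support with replicate boundary handling and are moment-matched
(zero sum, exact first/second moments) so that the discrete Hessian of a
constant image is exactly zero and of a quadratic exactly its analytic
value; an auto-calibrated scale whose structureness ceiling sits at
rounding-noise level is skipped rather than amplified; a constant image gives
zero structureness and, by convention, zero response (the `c = "auto"`
scale resolves to zero and the scale is skipped); min-max normalization
of a constant image is defined as the all-zero image to avoid 0/0.

## The synthetic phantom

The original in-vivo mouse brain/ear data are not deposited, so the
package generates phantoms with the same statistical roles: branching
bright curvilinear vessels on a dark background, rendered at two
wavelengths with oxygenation-dependent contrast. A vessel tree is grown
by depth-first recursive branching (each segment spawns 0–2 children at
probability 0.7 per side, child radius × U(0.6, 0.9), length ×
U(0.7, 0.95), direction rotated ± U(0.25, 0.7) rad); oxygenation is
drawn per root from U(0.55, 1) — spanning venous to arterial values —
and inherited down the tree, since oxygenation varies between vessels
far more than along one. Segments are drawn with an anti-aliased disk
brush; per-pixel absorption at wavelength λ is
`ε_HbO2(λ)·sO2 + ε_Hb(λ)·(1−sO2)` times coverage, blurred by a Gaussian
PSF (default FWHM 2.5 px), offset by a small background, and min-max
normalized **jointly** over the two channels. Joint (not per-channel)
normalization matters: it preserves the inter-channel intensity ratio
that carries the sO2 signal, so noiseless unmixing of the rendered
channels recovers the true sO2 exactly; the brighter channel spans
[0, 1]. The default extinction table (532 nm isosbestic; Hb > HbO2 at
560 nm) ships as a constants file in relative units.

What the phantom does not emulate: depth-dependent fluence, acoustic
reverberation, scan-axis artifacts, vessel crossings in depth, and the
texture statistics of real tissue. Passing tests therefore show the
pipeline behaves as reported *in kind* (restoration improves metrics,
masking preserves sO2), not that in-vivo magnitudes are reproduced.

## Evaluation

PSNR is `20·log10(max(ref)/√MSE)` in dB, with the peak taken from the
reference. SSIM is the three-term product (luminance, contrast,
structure) computed from **global** image statistics — the form printed
in the original description — with population (1/N) moments; constants
`c1 = (0.01L)², c2 = (0.03L)², c3 = c2/2, L = 1` for data on the (0,1)
scale (the original constants are unstated). A sliding-window variant is
available behind the `window` argument, but the global form is canonical
here. Line-profile SNR divides the peak of a bilinearly interpolated
profile by the SD of a vessel-free background box; the exact original
definition (peak vs mean, background choice) is unstated, so the
peak/SD form is a documented choice. Distribution summaries use the
sample (n−1) SD. Identical images make PSNR infinite; this is signaled
as an explicit condition rather than returning `Inf` silently.

## sO2 estimation

Per pixel, `[pa532; pa560] = E [C_HbO2; C_Hb]` is solved with the 2×2
extinction matrix; `sO2 = C_HbO2 / (C_HbO2 + C_Hb)`, clipped to [0, 1],
undefined where the total concentration is non-positive. Because images
are min-max normalized, absolute concentrations are meaningless, but
sO2 — a per-pixel ratio — is invariant to any common rescaling of the two
channels, which joint normalization preserves. Masking by a thresholded
vessel image (the original workflow compares the raw image, the
vesselness-filtered image, and the fused reconstruction as mask sources)
selects pixels and never edits the retained values.

## Desk-scale study conditions

The end-to-end check trains on 16 of 20 synthetic 128×128 scenes
(f = 1/2, s = 2, noise SD 0.05), 500 Adam steps at batch 2 on 32×32
low-resolution patches, and evaluates on the 4 held-out scenes: the
fused reconstruction must beat nearest-neighbor upsampling of the 532 nm
input against the vessel-enhanced target by at least 1 dB PSNR and 0.02
SSIM, and the 100-step moving average of the training loss must fall.
These problem sizes are the package's chosen desk-scale conditions — two
orders of magnitude below the original training corpus of several
thousand in-vivo tiles — so
the absolute PSNR/SSIM values printed for the in-vivo data are out of
reach by design; the *ordering* of methods is what the check preserves.

## Known limitations

* Training is CPU-bound and single-threaded; the full-scale RDN profile
  is configurable but not practical without substantial compute.
* The Frangi-based target inherits the filter's known behavior of
  thinning/merging adjacent vessels; the fused output is trained toward
  it and therefore inherits a softened version of that bias.
* Checkpoints serialize with R's native RDS format (with a JSON metadata
  header embedded); they are not interchangeable with other frameworks.
* Patch datasets are assembled in memory; at desk scale this is a few
  hundred megabytes at most.
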
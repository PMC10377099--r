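---
title: "Deep-feature fusion of structural and functional slices: methods"
author: "fusionet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-feature fusion of structural and functional slices: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionet)
```

## The model

`fusionet` fuses two (or more) co-registered single-channel slices into one
image that preserves the anatomical detail of the structural modality and
the salient activity of the functional one. The method is weight-map
fusion in a deep-feature domain:

* A fixed-weight VGG-style backbone maps each source `I_z` to per-block
  feature stacks `f_z^y` (ReLU outputs of the last convolution of block
  `y`; blocks downsample by 2 each, so block `b` has spatial side
  `ceiling(side / 2^(b-1))`).
* Channel collapse gives an activity map per source and block; a per-pixel
  softmax across sources turns activities into convex weights
  `W_z^y` summing to 1 at every pixel.
* Each source is enhanced by one untrained transposed-convolution layer
  and combined under its weights; the final image is the per-pixel maximum
  over the per-block fused images.

Three modeling assumptions matter. First, the backbone is a *fixed*
nonlinear feature map, not a trained classifier: relative feature
magnitudes between sources, not absolute semantics, drive the weights, so
seeded random ("fixture") weights exercise the identical algebra as
pretrained filters and keep every result bit-reproducible offline. Second,
the sources are assumed registered before fusion; the preprocessing module
(morphology, shift, rotation, sharpening) is a programmatic stand-in for
the manual alignment such pairs usually receive, with defaults of zero
(inputs presumed pre-registered). Third, pseudo-color functional input is
collapsed to BT.601 luminance before entering the grayscale fusion path.

## Design choices where the design was open

**Softmax, exactly.** The weight rule is implemented as a true softmax —
exponential in numerator and denominator — with the per-pixel maximum
subtracted before exponentiation. Shift invariance makes the subtraction
exact while preventing overflow for large activities.

**Activity collapse.** Both the channel *sum* and the channel *mean* are
offered; the default is the mean, because block channel counts range from
64 to 512 and the mean keeps activity scales comparable when several
blocks are tapped at once.

**The per-block operator.** Two readings of "weights times enhanced
source" are supported. The default `apply` mode computes
`sum_z W_z * TransConv(I_z)`: it is convex, so fusing an image with itself
under the identity kernel returns it bit-exactly, and the fused value at
each pixel stays inside the hull of the (enhanced) source values. The
literal `hadamard` mode, `sum_z W_z * I_z * TransConv(I_z)`, squares
intensities and therefore darkens mid-tones and breaks the self-fusion
identity; it is retained as a config option for fidelity, not as the
default.

**Transposed-convolution geometry.** The enhancement layer defaults to
K = 3, S = 1, P = 1, implemented as standard scatter-add transposed
convolution with output side `(H - 1) S - 2P + K` — shape-preserving for
the default, matching the layer's size-restoring purpose; a 1 x 1 kernel
remains available through the spec. The kernel is untrained (no training
signal is defined for the fusion path), and its default init is the
identity, which makes the enhancement a strict, testable no-op baseline;
`smoothing` (binomial) and seeded `random` inits are provided for the
ablation grid.

**Weight maps at image resolution.** Activity maps computed at block
resolution are upsampled (bilinear by default; nearest optional) *before*
the softmax, which guarantees the per-pixel sum-to-one property holds
exactly on the full-resolution fusion grid. Deeper taps therefore fuse
full-resolution images under increasingly blocky weights — the upsampling
artifact that motivates examining tap depth.

**Default tap depth.** Shallow features carry the fine spatial detail a
fused image should keep, and the depth ablation (below) confirms the
shallow-is-better direction on phantoms, so `tap_blocks = 1` is the
default; any subset of blocks 1–5 may be tapped, with max-selection
reconstruction across them.

**Morphology semantics.** Dilation and erosion use the standard textbook
definitions (neighborhood max and min over a flat structuring element,
out-of-frame neighbors ignored); either op can be assigned to either
modality in the preprocessing recipe. Border policy is zero-fill for the
geometric ops (nothing is invented outside the frame) and reflect padding
for kernel sharpening (energy-preserving at edges). Rotation is
counter-clockwise-positive in screen coordinates (origin top-left, y
down), bilinear, about the image center.

**Metrics.** SSIM uses the universal constants: 11 x 11 Gaussian window
with sigma 1.5, K1 = 0.01, K2 = 0.03, L = 1, local moments in valid mode
(no padding), averaged over the valid region. PSNR is `10 log10(1/MSE)`
with an infinity sentinel for identical images, serialized as `"inf"`.
Entropy uses 256 equal-width bins on [0, 1] (8-bit convention), final bin
right-inclusive. Because no ground-truth fused image exists, reports score
fused-vs-source, one row per source modality.

**Pareto machinery.** Dominance and front extraction are generic over
named hyperparameters, any number of objectives, and per-objective
directions; feasibility filtering is a user-side predicate applied before
front extraction. Scalarization min-max normalizes each objective over the
candidate set before weighting — mandatory when mixing a unit-scale
quality loss with parameter counts in the millions — and selection is
restricted to the front, so a dominated candidate can never win on
scalarized score alone. Ties break toward the lower first objective, then
input order. The shipped candidate grid (`demo_candidates()`) varies tap
block, activity collapse and enhancement init, scored by
`1 - mean SSIM against the sources` and the tapped sub-network's parameter
count, so the machinery is exercised with no training data.

## The phantom generator

`make_phantom_pair()` emulates the *contrast structure* of a registered
MRI/PET pair: the structural slice has sharp boundaries (bright skull
ring, textured tissue, dark ventricles, a few hard-edged lesions — high
high-frequency energy), while the functional slice is a smooth uptake
field (broad base metabolism plus Gaussian hotspots) strictly inside the
same anatomy, rendered through a black-red-yellow-white hot colormap so
the luminance path is exercised on realistic input. The spec controls
side length (default 128), seeded misalignment (returned as ground
truth), Gaussian noise (default sigma 0.01, mild sensor noise) and
hotspot count (default 3). Geometry is parametric ellipses and Gaussian
blobs, fully seeded, with no hidden global RNG state.

What the phantoms do *not* emulate: acquisition physics (partial volume,
attenuation, scanner-specific noise spectra), anatomical variability, or
inter-modality intensity relationships of real clinical pairs. Passing
tests therefore certify the *algebraic* correctness and determinism of
the pipeline and the directional behavior of its metrics on
known-structure inputs — not clinical image quality.

## Numerical choices and degenerate inputs

* All images live in [0, 1]; every preprocessing op preserves shape and
  range, and fusion clips to [0, 1] only where non-identity enhancement
  kernels can overshoot.
* Weight sums are exact to machine epsilon (verified to 1e-6 across
  random activity sets); softmax stability comes from max subtraction,
  not clamping.
* Fixture weights are He-initialized with zero biases, so an all-zero
  image produces all-zero features at every depth.
* 2 x 2 max pooling uses ceil mode (odd sides keep their last row/col),
  matching the `ceiling(side / 2^(b-1))` bookkeeping; phantom sides are
  powers of two so the question rarely arises in practice.
* Empty structuring elements, out-of-range shifts, non-finite angles,
  shape mismatches, empty candidate lists and non-positive
  transposed-conv output sizes are rejected with invalid-argument errors.
* 16-bit PNG output uses the package's own minimal encoder (filter-0
  scanlines, zlib stream) because the installed PNG writers are 8-bit
  only; round-trip error is bounded by 1/65535.

## Problem sizes

The test suite and acceptance script run, by the package's choice, on
128 x 128 phantoms (64 x 64 for unit-level checks), vgg11 for batch
experiments and vgg19 for the default single-pair configuration, with
10-pair batches for the quality averages and the block-1 vs block-5 depth
comparison, and a 20-cell candidate grid scored on 3 phantoms for the
Pareto demo. These sizes keep the full suite under a minute while leaving
every contract representative; all of them scale with the corresponding
arguments.

## Known limitations

* No trained weights ship with the package; fixture features are
  statistically unlike ImageNet-trained filters, so absolute metric
  values on real data will differ (the `file` weight source accepts
  exported pretrained weights).
* The depth-ablation direction (shallower taps scoring higher mean SSIM)
  is a statistical tendency of feature resolution, not an algebraic
  identity; the acceptance suite treats it as a soft, reported check.
* Only 2D slice fusion is implemented — no volumetric or deformable
  registration; DICOM input is not supported (no reader in the
  dependency set), NIfTI slices and PNG/TIFF are.
* The Pareto module enumerates supplied candidates; it does not search.
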
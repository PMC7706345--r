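---
title: "Measuring root distribution on trench profile walls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring root distribution on trench profile walls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trenchroot)
```

## The measurement problem

The trench profile method exposes a vertical soil wall next to a crop
plant; the roots visible on that wall carry the information a breeder
wants about where the plant forages — how deep and how wide the root
system spreads. Quantifying them by hand means tracing every root on
every photograph, which is the bottleneck of the whole method.

`trenchroot` implements the full measurement chain:

1. **Frame normalization.** Field photographs are mapped into a fixed
   60 cm x 60 cm frame at 25.6 px/cm (256 dots per 10 cm), soil surface
   at row 0, planting position ("hill") at the centre column. The
   per-image rotation, scale and crop are manual annotations supplied in
   a sidecar table; lens distortion is assumed corrected upstream.
2. **Segmentation.** A U-shaped fully convolutional network labels each
   pixel as root or soil. The frame is processed as a 6 x 6 grid of
   256-px tiles, predicted tile by tile and reassembled in the original
   order.
3. **Phenotyping.** The binary mask is folded in half about the hill
   column (OR of mirror columns), thinned to a 1-px skeleton, and
   summarized by cumulative-length quantiles: **Depth50** is the depth
   below which 50% of total root length lies, **Width50** the analogous
   distance from the hill. One skeleton pixel corresponds to
   10/256 cm ≈ 0.39 mm of root length.
4. **Statistics.** Pearson validation of predicted vs. manually traced
   parameters; broad-sense heritability from variance components;
   one-way ANOVA across acquisition dates; Steel–Dwass all-pairs
   subspecies comparison; hierarchical clustering of z-scored traits.

A seeded synthetic-image generator stands in for field photographs, so
every stage is testable end to end without field data.

## The segmentation network

The network is the classic encoder/decoder with skip connections,
modified in three ways: 3x3 convolutions are zero-padded so tiles keep
their size, batch normalization follows every convolution *and* every
down/up-sampling step, and the head is a single sigmoid channel (the
only class is "root"). Defaults are 4 resolution levels starting at 64
channels on 256-px tiles; training uses Adam at learning rate 0.001,
iterating every training pair once per epoch (a 10-image training set
yields 360 tile pairs per epoch), for 500 epochs at field scale.

Because no deep-learning framework is available to R here, the network
is implemented inside the package (Rcpp/RcppArmadillo): im2col
convolutions, batch statistics, 2x2 max pooling, nearest-neighbour
upsampling, and analytic backpropagation for every parameter. The test
suite verifies the gradients against central finite differences for
both loss choices, so the training loop rests on checked calculus, not
on faith.

Choices the source protocol leaves open, fixed here once:

* **Loss**: binary cross-entropy by default ("dice" selectable); the
  Dice coefficient is always tracked as the evaluation metric.
* **Batch size** 4; **binarization threshold** 0.5 with a strict
  inequality (a pixel at exactly the threshold is background).
* **Dice granularity**: aggregate ("micro") over all validation pixels.
* **Test-scale preset** (`model_config(test_scale = TRUE)`): 3 levels,
  8 base channels, 64-px tiles. Synthetic imagery for desk work is
  generated at 6.4 px/cm so the 60-cm frame is 384 px and still
  divides into the canonical 6 x 6 tile grid.

Augmentation applies a shared geometric transform (horizontal flip,
rotation ±15°, scale 0.9–1.1) to image and mask — the mask
nearest-neighbour so it stays binary — and photometric transforms
(intensity 0.8–1.2, gamma 0.7–1.4, chroma 0.8–1.2) to the image alone,
in the fixed order flip, rotate, scale, intensity, gamma, chroma, one
uniform draw each. Epoch streams are pure functions of
`(seed, epoch index)`.

## Phenotype definitions and numerical choices

Folding combines columns at equal hill distance by logical OR, not by
addition: the folded object is still an image, which is then thinned.
Two roots at mirror positions therefore merge — a documented
limitation of fold-then-skeletonize order.

Thinning is Zhang–Suen; it erodes up to half the stroke width at each
curve end, so a 4-px-wide bar of length L skeletonizes to roughly
L − 4 pixels. At 0.39 mm per pixel this is ~1.6 mm per root end, well
below biological variation. The quantile is "smallest bin where the
cumulative fraction reaches q", interpolated linearly inside the
crossing bin; bins are 1 px, so interpolation is below measurement
noise either way. Empty masks raise an error ("no roots detected")
rather than producing zero phenotypes — a failed segmentation should
be re-traced, not averaged in as a rootless plant.

Heritability uses the one-way random-effects estimator:
`V_G = (MS_accession − MS_error) / r` with `r` the harmonic-mean
replicate count, clipped at zero, `V_P = V_G + MS_error`,
`H² = V_G / V_P`. The trait definition gives the ratio only; this
estimator is the standard choice for plot-replicated field traits with
about three replicate images per accession. The "neighbour method" for
clustering is read as nearest-neighbour (single) linkage on Euclidean
distances of z-scored per-accession means, cut at k = 5 by default;
complete linkage is available where chaining is a concern. Steel–Dwass
uses midrank ties and the large-sample studentized-range reference
(`q/√2` convention); exact enumeration is out of scope.

## What the synthetic generator does and does not emulate

Each synthetic image is a textured soil background (correlated
low-frequency noise, fine grain, a vertical illumination gradient and
per-image contrast jitter, with "topsoil" and "subsoil" palettes) under
a fan of lighter root strokes. Roots emerge within ±2 cm of the hill,
follow outward rays whose slope grows with their emergence distance
(so the fan never crosses itself, even after folding), carry a bounded
sinusoidal wiggle, and place **exactly one centerline pixel per row**.
Terminal depths are drawn as `min(Exp(rate), 60 cm)`, which makes the
depth density of centerline pixels exactly the truncated exponential
with that rate — so Depth50 has a closed form,
`-log(1 - 0.5 (1 - e^{-60λ})) / λ`, against which the pipeline is
tested. Truth parameters are computed from the exact centerline paths
(with multiplicity where curves touch), bypassing segmentation and
thinning: the oracle route.

The truth mask is the centerline dilated to the 4-px pencil width used
in manual tracing, while rendered strokes take independent widths of
2–6 px — labels are deliberately width-mismatched with appearance,
as manual tracing is.

Emulated: label-width conventions, illumination and soil-colour
variation, depth-law diversity across accessions (per-image rates drawn
from a configurable range, default 0.03–0.14 /cm, spanning roughly
5–18 cm in Depth50). Not emulated: stones, cracks, worm channels,
specular water films, root branching topology, photorealistic texture.
Passing the desk-scale tests therefore shows the pipeline's machinery
is correct and learnable, not that the model generalizes to field
photographs.

One interaction deserves honesty: at the desk-scale resolution
(6.4 px/cm) with 40 roots, dilated strokes fuse near the crown, and
the skeleton of the fused mask under-counts root length there, so
skeleton-derived Depth50 sits systematically deeper than the
centerline truth. The generator↔estimator loop closes within 0.5 cm
only where strokes rarely touch — verified at full resolution with
8-root fans. The train/validate acceptance check instead scores the
*correlation* between truth and predicted Depth50 across images, which
is robust to that shared monotone bias; the package reports it
alongside the held-out Dice.

## Problem sizes used in the bundled checks

The test battery and the acceptance script run entirely at desk scale,
chosen as the smallest sizes at which every behaviour is still
exercised: 26 synthetic images (10 training — exactly 360 tile pairs,
mirroring the field training-set size — and 16 held-out), the
test-scale network trained 6 epochs, heritability averaged over 200
draws of 60 accessions x 3 replicates, and ANOVA calibration over
1000 seeded 7-group null replicates. Field-scale defaults (1536-px
frames, 4-level/64-channel network, 500 epochs) are the documented
configuration for real use.

## Known limitations

* Fold-then-skeletonize merges roots that overlap after folding.
* Whole-image prediction uses disjoint tiles with no overlap blending;
  seam artifacts are possible and accepted (the reference protocol
  reassembles disjoint tiles).
* The heritability estimator ignores genotype-by-environment structure
  (one year, one location is the intended design).
* The CNN here is CPU-bound; field-scale 500-epoch training is outside
  the scope of this implementation's performance envelope, though the
  code path is identical.
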
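---
title: "Calcified cartilage morphometry: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calcified cartilage morphometry: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Calcified cartilage (CC) is the thin mineralized layer between the tidemark
(its boundary with non-calcified articular cartilage) and the cement line
(its boundary with subchondral bone). Its thickness, CC.Th, is a morphometric
endpoint of interest in cartilage physiology and osteoarthritis research.
Delineating CC is easy in stained histology sections but hard in micro-CT,
where the mineralization contrast between CC and bone is subtle; manual
slice-by-slice annotation of 3D stacks is prohibitively slow and subjective.

`ccmorph` implements an automated pipeline for this measurement: an
encoder-decoder convolutional network segments the CC layer in 2D images
(histology-like) or slice-wise in 3D stacks (micro-CT-like); the binary
masks are cleaned with a small set of morphological rules; and CC.Th is
quantified by local thickness — the diameter of the largest inscribed disc
(2D) or sphere (3D) through each foreground element. Because the original
animal images and annotations are not distributable, every stage is
developed and validated against synthetic osteochondral phantoms with
analytic ground truth.

## The phantom generator

A phantom stacks three intensity phases along the depth axis: articular
cartilage (dark, mean 0.25), a CC band (intermediate, 0.55) and bone
(bright, 0.85 with multiplicative speckle so the CC/bone boundary is a
gradient rather than a step — the hard case in real micro-CT). The band's
local vertical thickness at lateral position $x$ is

$$ t(x) = b + a \sin(2\pi x / T) + \varepsilon(x), $$

with base $b$, amplitude $a$, period $T$ and smoothed zero-mean roughness
$\varepsilon$; in 3D the sinusoid is separable over the two lateral axes.
Dark chondrocyte-like voids (discs/balls, radius 2–4 px) are placed fully
inside the band and belong to the truth mask, matching the annotation
convention in which intra-CC cavities are part of the layer; an exclusion
toggle exists. Additive Gaussian noise (sd 0.04) is applied last and the
image is clipped to $[0,1]$. A phantom is a deterministic function of its
specification and seed.

Default study conditions were fixed once: 2D images of 128 × 192 px at
2.56 µm/px with $b$ cycling over {26, 30, 34, 38} px across phantoms
(66–97 µm, emulating the thin-tibial to thick-patellar anatomical range),
$a = 8$ px, $T = 128$ px, roughness 1 px; 3D volumes of 64³ voxels at
3.2 µm/px with $b = 16$ px, $a = 4$ px, $T = 64$ px. Two geometric
constraints motivated these numbers. First, the 12-px median filter
prescribed by the cleaning chain preserves a straight band edge exactly when
the band thickness is at least the filter radius (an edge element sees an
exact half/half split, and ties resolve to foreground), so all bands stay
≥ 12 px thick everywhere. Second, inscribed spheres must stay small relative
to the lateral field of view, because the declared thickness convention
treats everything outside the image as background and therefore clips
spheres at the volume faces; at 64³ a 16-px band (sphere radius ≤ 10) keeps
this boundary bias second-order, which mirrors the real geometry where a
~25 px band sits in a ~625-px-wide crop.

What the phantoms do *not* model: X-ray physics (beam hardening, partial
volume), multiple tidemarks, pathology, or truly ambiguous CC/bone
interfaces. Passing the phantom study therefore demonstrates that the
pipeline is internally correct and recovers known geometry through realistic
contrast and noise — not that the bundled training protocol reaches
publication-grade accuracy on real tissue.

## Segmentation model and training

The network family is a grayscale-in, probability-out encoder-decoder with
four scales (downsampling factor 8). Encoders: a `small` preset (one
convolution block per scale) for CPU-scale work, and residual presets whose
block counts follow the 18-layer (2-2-2-2) and 34-layer (3-4-6-3) designs.
Decoders: `full_resolution_skip` (U-Net style: upsample, concatenate the
skip, convolve) and `pyramid` (FPN style: 1×1 lateral projections, top-down
additions, per-scale heads summed after upsampling to full resolution, so
the output passes through a final upsampling). Normalization is batch or
instance; spatial dropout zeroes whole channels during training. The whole
engine — im2col convolutions on BLAS, pooling, nearest upsampling,
normalization, reverse-mode tape — is implemented in the package and its
gradients are verified against numeric differentiation in the test suite.

The training loss is the sum of mean per-pixel binary cross-entropy and one
minus the soft Jaccard index,
$J = (\sum pt + \epsilon)/(\sum p + \sum t - \sum pt + \epsilon)$ with
$\epsilon = 10^{-7}$; BCE gives stable convergence and the Jaccard term
counters the class imbalance between the thin CC band and everything else.
The relative weighting of the two terms is a free choice; the default is
1:1, configurable. Gradients are taken in logit space (the BCE term then reduces
to $(p - t)/n$), which stays informative where the sigmoid saturates.

Cross-validation is grouped by subject: the sorted subject list is shuffled
by the seed and dealt round-robin into folds, so no subject's images can
appear on both sides of any fold. Defaults follow the protocol scale:
4 folds, 100 epochs for histology / 60 for micro-CT, Adam (the optimizer is
not named by the protocol; an adaptive-moment method is the natural choice)
at learning rate 1e-3, random tile crops matching the inference tiling
geometry, and an augmentation set (flips, ±15° rotation, ±10% scale, ±20%
brightness/contrast, gamma 0.8–1.2, mild noise) standing in for parameters
that are not published in detail. The desk-scale study uses the small
encoder, 20 epochs, and four 64×64 crops per image per epoch — the step
count, not the epoch count, is what matters on an 8-image training set.
Out-of-fold Dice during training is evaluated at threshold 0.5 on raw
per-tile predictions; the deployment threshold of 0.8 below is a separate,
deliberately conservative choice.

## Inference and post-processing

Full images are predicted by a sliding window (deployment default
512 × 1024 px windows, 256 × 512 px steps), overlapping predictions averaged
uniformly; the final row/column of windows is shifted inward so windows
never leave the image, and images smaller than one window are reflect-padded
and cropped back. Fold models are ensembled by uniform averaging, and for
volumes the per-slice predictions of the coronal and sagittal planes (row
and column axes of the (slice, row, column) convention) are averaged as
well; because all means are uniform, a single mean over (fold × plane)
members is equivalent to sequential averaging. The probability map is
thresholded at 0.8 — inclusive at the threshold — to exclude ambiguous
regions.

Cleaning follows the modality: histology masks drop connected components
smaller than 500 px (strictly smaller: a 500-px component survives, and
large disconnected CC pieces are kept); micro-CT masks keep only the largest
3D object (ties broken by smallest first voxel coordinate, for
determinism); both are then median-filtered with radius 12 px (3D ball for
volumes). The median is a binary majority over a Euclidean disc/ball,
computed by FFT convolution with integer rounding (exact counts), with
reflective boundaries and ties resolving to foreground so thin structures
are not eroded. Connectivity is 8 in 2D and 26 in 3D by default — maximal
connectivity avoids splitting thin diagonal CC bridges.

## Local thickness

The discrete convention is fixed as follows: `EDT(c)` is the Euclidean
distance from foreground element $c$ to the nearest background element
*centre*, with everything outside the image treated as background, and

$$ \tau(p) = 2 \max \{\, \mathrm{EDT}(c) : c \text{ foreground},\;
   \lVert p - c \rVert < \mathrm{EDT}(c) \,\}. $$

All comparisons are made on exact integer squared distances (the package's
distance transform returns exact squared values), so the strict inequality
is unambiguous. The production path reduces candidate centres to a distance
ridge — a centre is discarded only when its inscribed ball is contained in a
neighbour's ball, an exact integer test, and containment implies a strictly
larger radius so simultaneous removal is safe — then paints the surviving
balls in decreasing radius order. This is an optimization only: the test
suite requires bitwise equality with a literal brute-force evaluation of the
definition on hundreds of random 2D and 3D masks.

Consequences of the convention worth knowing: an axis-aligned slab of
height $h$ has $\tau = h$ exactly at elements farther than $h$ from its
lateral ends (the slab law, asserted exactly in the tests), and thickness is
under-estimated within one ball radius of the image boundary (spheres are
clipped, never padded). Summaries (mean, median, max, population SD over
foreground elements, in µm) therefore carry a small negative boundary bias
and a small positive weighting bias (thicker columns contribute more
elements); both are second-order for bands that are thin relative to the
lateral extent. Per-sample values from multiple sections or slices are
combined as the unweighted mean of per-section means.

## Validation statistics

Segmentations are scored with the Dice coefficient (empty vs empty is
defined as 1 and flagged); method agreement uses two-tailed Pearson
correlation (p-value via the exact t transform on $n-2$ degrees of freedom,
through the standard library routine) and Bland–Altman analysis: bias =
mean difference, SD of differences with the sample ($n-1$) denominator —
the conventional Bland–Altman choice — and 95% limits of agreement at
bias ± 1.96 SD. The linear mixed-effects comparison across anatomical
regions is out of scope; the reports emit per-sample tables consumable by
external mixed-model software.

## The scaled study and what it shows

`phantom_study_2d()` is the package's reproducible end-to-end experiment:
12 phantoms (8 training subjects, 4 held out) with base thickness cycling
over the anatomical range, grouped 4-fold CV training of the small model for
20 epochs, then recovery of mean CC.Th through the full deployment pipeline.
Held-out phantoms are predicted with the complete fold ensemble; training
phantoms with their out-of-fold model only, so every number is produced by a
model that never saw that subject. The study reports per-phantom Dice and
thickness recovery, the Pearson correlation between prescribed and
recovered means, and a Bland–Altman comparison. The same experiment backs
`scripts/acceptance.R` and the acceptance tests; problem sizes (128×192
images, 64³ volumes, 20 epochs) are the package's chosen desk-scale
conditions.

## Numerical choices and degenerate inputs

- Probability clamping to $[10^{-7}, 1 - 10^{-7}]$ inside BCE; smoothing
  $\epsilon = 10^{-7}$ in the soft Jaccard (empty-vs-empty gives 1).
- He initialization from the model seed; batch-norm running statistics with
  momentum 0.1 are used at evaluation time.
- Thresholding is inclusive (≥); masks thresholded at increasing values are
  nested.
- Empty masks: thickness raises an error (no foreground to measure);
  largest-component on an empty mask warns and returns it unchanged;
  region removal passes empty masks through.
- Median-filter counts are FFT convolutions rounded to exact integers; a
  50/50 majority tie resolves to foreground.
- All randomness (phantoms, fold shuffles, initialization, crops,
  augmentation) derives from explicit integer seeds; identical
  configuration and seed reproduce every number bit-for-bit.

## Known limitations

- The thickness convention's boundary clipping biases measurements low
  within one ball radius of the image faces; crop generously around the
  structure of interest.
- The painting-based local thickness is quadratic-ish in band volume and
  meant for desk-scale volumes; distance-ridge algorithms with better
  scaling exist and the candidate-reduction hook is the natural place for
  them.
- The CNN engine is pure R: entirely adequate at phantom scale, but not a
  GPU training framework; the residual presets are provided for structural
  fidelity, not speed.
- Phantom realism is deliberately limited (see above); results on real
  histology/micro-CT require training on real annotated data with the
  full-scale protocol defaults.
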
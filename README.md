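# ccmorph

Automated segmentation and thickness morphometry of the calcified cartilage
(CC) layer in osteochondral images.

Calcified cartilage is the thin mineralized band between the tidemark (its
boundary with articular cartilage) and the cement line (its boundary with
subchondral bone). Its thickness, **CC.Th**, varies with anatomical location,
loading and joint disease, but measuring it in 3D is hard: in micro-CT the
mineralization contrast between CC and bone is subtle, and manual
slice-by-slice delineation is slow and subjective. `ccmorph` is for
musculoskeletal imaging researchers who want this measurement automated and
auditable end to end.

## What the package does

- **Segmentation**: an encoder–decoder convolutional network (U-Net-style
  skip decoder or feature-pyramid decoder over a small or residual 18/34-style
  encoder) maps grayscale tiles to CC probability maps. The training loss is
  the combination of binary cross-entropy and the soft Jaccard index

  $$L = \mathrm{BCE}(p, t) + \left(1 - \frac{\sum p\,t + \epsilon}{\sum p + \sum t - \sum p\,t + \epsilon}\right),$$

  optimized with Adam under subject-grouped fourfold cross-validation (no
  subject's images ever appear on both sides of a fold). The full CNN engine
  — im2col convolutions, pooling, batch/instance normalization, spatial
  dropout, reverse-mode autodiff — is implemented in R and its gradients are
  verified against numeric differentiation in the test suite.
- **Inference**: tiled sliding-window prediction (512 × 1024 px windows,
  256 × 512 px steps by default) with uniform overlap averaging, fold
  ensembling, and coronal/sagittal plane averaging for volumes; probability
  maps are thresholded at 0.8.
- **Post-processing**: histology masks drop regions smaller than 500 px;
  micro-CT masks keep only the largest 3D object; both are median-filtered
  with a 12 px Euclidean disc/ball.
- **Morphometry**: Hildebrand–Rüegsegger local thickness by discrete
  circle/sphere fitting, $\tau(p) = 2\max\{\mathrm{EDT}(c) : \lVert p-c\rVert < \mathrm{EDT}(c)\}$,
  computed on exact integer squared distances and tested bitwise against a
  brute-force oracle; summaries report mean/median/max/SD CC.Th in µm.
- **Agreement statistics**: Dice score, two-tailed Pearson correlation, and
  Bland–Altman bias with 1.96 SD limits of agreement.
- **Phantoms**: a synthetic osteochondral image generator (three intensity
  phases, sinusoidally varying band thickness, chondrocyte-like voids,
  noise) with analytic ground truth, so the whole pipeline is testable
  without animal data.

See `vignettes/ccmorph-methods.Rmd` for the conventions, parameter defaults
and design decisions.

## Worked example

```r
library(ccmorph)

# a synthetic osteochondral image with known band geometry
ph  <- generate_phantom_2d(phantom_spec(seed = 42))
pre <- prescribed_mean_thickness_um(ph)

# local thickness of the ground-truth CC band
tmap <- local_thickness(ph$truth_mask)
s    <- summarize_thickness(tmap, sample_id = "phantom42")

cat(sprintf("prescribed mean CC.Th: %.2f um\n", pre))
cat(sprintf("recovered:  mean %.2f, median %.2f, max %.2f, sd %.2f um over %d px\n",
            s$mean_um, s$median_um, s$max_um, s$sd_um, s$n_foreground))
#> prescribed mean CC.Th: 86.27 um
#> recovered:  mean 93.03, median 98.49, max 102.40, sd 13.39 um over 6481 px

# method agreement between two sets of per-sample CC.Th measurements
ba <- bland_altman(c(95.1, 80.3, 71.9, 101.2), c(91.4, 81.2, 70.9, 101.6))
cat(sprintf("Bland-Altman: bias %.2f um, SD %.2f um, LoA [%.2f, %.2f]\n",
            ba$bias, ba$sd_diff, ba$loa_low, ba$loa_high))
#> Bland-Altman: bias 0.85 um, SD 2.06 um, LoA [-3.19, 4.89]
```

The recovered mean sits a few percent above the prescribed value: thicker
columns contribute more pixels to the mean (a weighting bias) while image
boundaries clip inscribed discs (a negative bias); both effects are
discussed in the methods vignette.

The complete scaled experiment — 12 phantoms whose base thickness cycles
over an anatomical range, grouped CV training of the small model, full
deployment pipeline, out-of-fold and held-out evaluation — is one call:

```r
st <- phantom_study_2d(seed = 1)
st$heldout_mean_dice   # mean Dice of held-out phantoms
st$pearson$r           # prescribed vs recovered mean CC.Th
```

An end-to-end run directory (resolved config, checkpoints metadata, summary
and agreement tables, logs) is produced by `run_end_to_end()`, and a thin
CLI wraps the same functions:

```sh
exec/ccmorph phantom --dim 2 --n 4 --out phantoms/
exec/ccmorph run --config demo.yaml --seed 1 --out runs/demo
```

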
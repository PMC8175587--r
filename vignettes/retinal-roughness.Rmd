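---
title: "Quantifying retinal layer roughness by box-counting fractal dimension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal layer roughness by box-counting fractal dimension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroughness)
```

## The problem

In early Alzheimer's disease (AD), thinned and thickened patches coexist
within most retinal layers.  Neither mean thickness nor any single-scale
statistic captures this: what changes is the *topographic complexity* of
each layer's thickness map across a whole range of spatial scales — its
roughness.  This package quantifies that roughness as the grayscale
box-counting fractal dimension (FD) of the layer's en-face thickness map: a
single number in [2, 3], slightly above 2 for real retinal layers, larger
when the map is rougher.  Around that estimator it implements the full
analysis chain used to evaluate layer roughness as an AD biomarker, and a
synthetic-cohort generator with known ground-truth roughness so every stage
is testable without clinical data.

## The pipeline

Each eye enters as a stack of 11 boundary surfaces on the scanner grid
(512 x 128 A-scan samples, voxel 11.7 x 46.9 x 3.5 um) with a segmentation
validity mask and two landmarks (foveal and papillary centers).  The stages
are:

1. **Left-eye mirroring** so temporal/nasal retina occupy the same columns
   in all subjects.
2. **Raw thickness**: `z_(k+1) - z_k` along the A-scan direction for each
   of the 10 layers.
3. **Orthogonal (cosine) correction**: axial distances overestimate true
   thickness on tilted layers; each value is multiplied by
   `cos(theta) = 1 / sqrt(1 + |grad z|^2)`, with the gradient of the layer
   *mid-surface* taken by central differences in physical units.  The
   mid-surface is a deliberate choice — the source computation does not say
   which surface defines the tilt, and the mid-surface treats both bounding
   surfaces symmetrically.  Physical pitches matter: with the 4x
   anisotropic row pitch, a pixel-unit gradient would distort tilt badly.
4. **Spatial normalization**: a similarity transform (exactly determined by
   the two landmarks) places the fovea at the image center and the
   maculopapillary axis at 4.377 mm and 6.766 degrees, resampled bilinearly
   onto an isotropic 11.7 um grid.  Resampling to the finer native pitch
   minimizes information loss; whether the original analysis resampled
   isotropically, and at which pitch, is unstated, so this is a
   configuration default, not a reproduction claim.  Mask handling is
   conservative: any output pixel touched by an invalid or out-of-coverage
   source pixel is invalid.
5. **Central ROI**: the largest standardized fovea-centered square
   available across subjects, 2.555 mm, i.e. 218 x 218 px at 11.7 um/px.
6. **Fractal dimension** of each ROI map (below).
7. **Cohort statistics**: exact Mann-Whitney rank-sum comparisons of
   per-subject mean FD (one-sided, AD > control), per-layer rank-sum tests,
   paired t across the per-layer group means with Shapiro-Wilk and
   variance-ratio checks, one-sided Pearson correlation matrices against
   MMSE, visual acuity and age, PCA variance shares, and a two-factor
   maximum-likelihood model with KMO/Bartlett adequacy diagnostics.

## The roughness estimator

Differential box counting treats the coded map as a relief: the `M x M`
grid is partitioned into `s x s` blocks; over each block the relief spans
`floor(max/h) - floor(min/h) + 1` boxes of height `h = s G / M` (gray range
`G` fixed at 256 so box height is comparable across subjects; an adaptive
`G` would confound amplitude with roughness).  The box grid is anchored at
gray level 0.  `N_r`, the total count, is regressed on log scale; the FD is
the slope.

Two border conventions are provided.  `integer_ratio_dbc` (the default)
covers the borders with shrunken blocks so every pixel is counted at every
scale; `classic_dbc` truncates incomplete border blocks.  Two codings are
provided: `native_depth` (gray = thickness / 3.5 um, comparable across
subjects — the default) and `minmax_8bit` (per-map affine stretch onto
0..255, amplitude-invariant).  Running all four combinations and checking
that the group-difference sign agrees (`robustness = TRUE` in
`run_config()`) guards against coding artifacts.

Numerical choices that matter:

- **Fit abscissa.** The regression uses `ln(blocks per axis)` — i.e.
  `ceil(M/s)` (integer-ratio) or `floor(M/s)` (classic) — rather than
  `ln(M/s)`.  With border blocks the two differ by a remainder jitter that
  systematically biases *near-smooth* maps below slope 2; using the actual
  partition cardinality makes a constant map have slope exactly 2 under
  both border conventions, which anchors the estimator's theoretical range
  `2 <= fd <= 3` (asserted on every call, with a 0.05 discretization
  slack).
- **Scale schedule.** Integer sizes `2, 3, 4, 6, 8, 12, ...` capped at
  `M/4`: several blocks per axis survive at the coarsest scale and the
  schedule spans over a decade.  All scales enter the fit by default.
- **Degenerate inputs.** A constant map returns fd = 2 exactly; maps with
  invalid pixels inside the ROI are rejected (box counting has no
  principled treatment of holes), which at cohort level turns into subject
  exclusion with a logged reason.
- **Offsets.** With the floor-anchored box grid, adding a constant to a map
  preserves counts exactly only when the gray shift is a whole number of
  boxes; small offsets can perturb counts by a box boundary crossing.  This
  is inherent to the absolute-anchor convention and is documented rather
  than hidden.

A side effect of the cosine correction worth knowing: a perfectly uniform
layer draped over a rough substrate acquires a rough *orthogonal* thickness
map (the tilt factor varies), even though its raw map is constant.  Layer
FDs after correction are therefore not strictly independent across layers —
a real property of the method, visible in the synthetic tests.

## The synthetic cohort generator

The generator exists so that every downstream stage has a ground truth.
Layer thickness = smooth radial base profile + amplitude-scaled fractional
Brownian (fBm) perturbation, clipped at zero; surfaces are built by
cumulative summation from the inner limiting membrane, so non-crossing
holds by construction.  The fBm fields come from Fourier spectral synthesis
with power spectral density proportional to `f^-(2H+2)`; a surface with
Hurst exponent `H` has theoretical FD `3 - H`, giving the estimator a
closed-form anchor: estimated FD must fall with `H` (it does, with the
negative bias typical of box counting) and rise with amplitude at fixed
`H`.

Defaults and why:

- **Anatomy**: peripheral base thicknesses 20, 30, 30, 28, 26, 75, 25, 18,
  18, 22 um (NFL..RPE, totalling ~290 um), with a Gaussian foveal pit
  (85% depth, 0.4 mm radial scale) on the inner six layers only.
- **Roughness**: Hurst 0.3 and amplitude 10 um RMS for every layer.  These
  two were calibrated once so that the full-scale pipeline (native coding,
  218 px ROI) lands per-layer FDs in the 2.08-2.14 band observed on real
  retinas; they are the study conditions, not tuning knobs.
- **Latent structure**: two independent standard-normal factor scores per
  subject; factor 1 loads (1.5 um per unit score) on the inner/neural block
  plus RPE, factor 2 on the photoreceptor-related pair OSL + OPR —
  mirroring the two-block factor structure reported for real cohorts.
- **Group effect**: +0.5 um amplitude in the simulated-AD arm, which
  produces a full-scale mean-FD gap of roughly 0.005 — the order of the
  published group differences (0.002-0.006).
- **Covariates**: MMSE, visual acuity and age are linked linearly to the
  subject's mean amplitude elevation with fixed signs (negative, negative,
  positive) and group-specific clinical ranges (MMSE about 23.4 +/- 3.1,
  range 17-29 in the AD arm; 28.4 +/- 2.0, range 25-31 in controls); the
  slope magnitudes are free parameters of the generator.

What the generator does *not* emulate: OCT speckle and intensity artifacts,
segmentation error fields (beyond optional rectangular mask injection),
vertical B-scan misalignment, and any real anatomical asymmetry beyond the
radial pit.  Passing tests therefore demonstrate that the chain of
estimators behaves correctly on controlled inputs with known truth — not
that clinical effect sizes are reproduced.  The published per-layer FD
values themselves are reproducible only from the deposited clinical
thickness dataset, for which `read_figshare_thickness()` is a thin adapter
left untested by design.

## Statistical choices

- The Mann-Whitney test reports the first sample's *rank sum* `W` (the
  convention whose published values exceed `n1 n2`) alongside `U`; the
  p-value is exact, from the permutation distribution of the rank sum
  computed by dynamic programming over doubled mid-ranks, so ties are
  inside the exact distribution (no approximation fallback is needed below
  60 combined observations).
- One-sided directions are fixed a priori: roughness higher in AD;
  correlations positive among layers and with age, negative with MMSE and
  visual acuity.  Everything else is two-sided.
- No multiple-testing correction anywhere: raw p < 0.05 is flagged, which
  mirrors the analysis this package models and is a documented caveat, not
  a recommendation.
- Factor extraction is maximum likelihood (`factanal`), which supplies the
  chi-square sufficiency test with df `((p-k)^2 - p - k)/2`; rotation is
  varimax — the standard orthogonal rotation, chosen because the modeled
  analysis implies orthogonal factors but never names its rotation.  Factor
  order is arbitrary, so block identification matches dominant loadings,
  not column indices.  Solutions with a uniqueness at the optimizer bound
  are flagged as Heywood-adjacent.
- Every statistic is cross-checked in the test suite against an
  independently coded reference path (hand-coded formulas, full
  enumeration, or the corresponding base-R test).

## Problem sizes used by the tests

The replicate-heavy simulations run at reduced conditions chosen once: an
isotropic 48 x 48 grid (11.7 um pitch) with a 40 px ROI.  At that scale one
subject costs ~25 ms, the estimator noise is small relative to a 3 um
loading scale, and both the 50-cohort factor-recovery study (n = 200 per
cohort) and the 200-cohort null-calibration study complete in minutes.
Full-scale (512 x 128, 218 px ROI) runs appear in the single-subject
regression fixtures and in the acceptance script's 43-subject cohort.  The
factor-recovery conditions use `loading_scale = 3` so that the induced
between-layer FD correlations match the 0.4-0.7 range seen in real
cohorts; the sufficiency test at n = 200 typically *rejects* two factors
for pipeline-generated data — the FD response to amplitude is mildly
nonlinear, so the exact two-factor hypothesis holds only for directly
simulated Gaussian data, which is how the sufficiency test is exercised.

## Known limitations

- The integer-ratio border convention published for grayscale box counting
  has several variants; equivalence with any specific binary is not
  claimed, and absolute FD values carry estimator bias (visible against the
  `3 - H` anchor).  Comparisons *between* groups processed identically are
  the intended use.
- The cosine correction propagates substrate tilt into deeper layers (the
  draping effect above).
- Box counting requires a fully valid square ROI; subjects with
  segmentation failures inside it are excluded rather than inpainted.
- Stage outputs are recomputed on every run; with deterministic seeds and
  desk-scale runtimes a content-addressed cache would add machinery without
  benefit, so none is included.
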
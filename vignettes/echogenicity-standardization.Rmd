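---
title: "Echogenicity quantification of EUS frames: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Echogenicity quantification of EUS frames: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eusbright)
```

## Overview

`eusbright` quantifies the brightness of gastric mesenchymal tumors on
endoscopic ultrasonography (EUS) still frames. Because the gray scale of an
EUS frame depends on per-examination gain and contrast settings, raw
brightness values are not comparable across acquisitions. The package
standardizes each frame against two structures whose appearance varies
least — the scope's anechoic (dark) transducer core and the hyperechoic
(bright) rim around it — and then summarizes a manually delineated tumor
region of interest (ROI) by its mean brightness `T_mean` (echogenicity) and
brightness standard deviation `T_SD` (heterogeneity). A lesion is predicted
to be a GIST when `T_mean >= 65` or `T_SD >= 75`.

This vignette records the model assumptions, the tunable parameters, and
the design decisions taken where the procedure was genuinely open.

## The anchor-extraction chain

`extract_scope_anchors()` runs, in order: histogram smoothing, Sobel
gradient computation, edge linking, binarization, grassfire
connected-component labeling, and morphological noise removal. The chain's
open parameters, all overridable through the `config` argument:

| parameter | default | units | rationale |
|---|---|---|---|
| `th` | 130 | gray levels | edge-linking tolerance: 8-neighbors whose gradient magnitudes differ by at most `th` are linked |
| `seed_quantile` | 0.9 | — | linking starts from pixels at or above the 90th percentile of nonzero gradient magnitudes |
| `min_area` | 30 | px | components smaller than this are noise |
| `min_circularity` | 0.3 | — | `4πA/P²` floor; rejects thin streaks as center candidates |
| `dark_margin` | 5 | gray levels | a center candidate must be at least this much darker than the frame mean |
| `transducer_position` | image center | (row, col) | real frames place the probe centrally; override for off-center probes |
| `rim_width_factor` | 1.2 | × center radius | width of the ring searched for rim pixels |
| `radial_tol` | 5 | gray levels | slack in the radial local-maximum test, on the order of typical speckle |

Decisions that deserve justification:

- **Gradient operator.** The procedure requires a gradient magnitude but no
  specific operator; the 3×3 Sobel pair with symmetric (reflective) border
  padding is the standard choice. Magnitudes are linearly rescaled to
  \[0, 255\] inside `link_edges()` before thresholding, so `th = 130` is a
  brightness-scale quantity rather than a raw-Sobel one.
- **Edge-linking seeds.** "All edge pixels" needs an initial edge set. We
  seed at the 90th percentile of nonzero magnitudes (inclusive, so a
  constant positive gradient map seeds everywhere) and grow to a fixed
  point. Growth is the closure of a symmetric relation, hence independent
  of pixel visiting order.
- **Connectivity.** 8-connected throughout: linking operates on a 3×3
  neighborhood, and labeling follows suit. `label_components()` accepts
  `connectivity = 4` for completeness.
- **Binarization.** Otsu's between-class-variance criterion by default,
  with the inclusive convention foreground = `pixel >= threshold`. A
  constant image has no valid split and yields all background.
- **Center selection.** Global Otsu can merge a dark-ish background with
  the transducer core. The dark threshold is therefore refined
  coarse-to-fine: if the candidate component nearest the transducer covers
  more than 40% of the frame, Otsu is re-applied within it (up to 3
  rounds). Ties between equidistant candidates break toward larger area,
  then lower mean gray. A candidate not darker than the frame mean by
  `dark_margin` raises "scope center not found" — this is what a uniform
  frame produces.
- **Rim selection.** Pixels in a ring just outside the center component
  qualify when they are bright (above the ring's own Otsu split, a local
  criterion that ignores the far-field background) and are radial local
  maxima within `radial_tol` gray levels. With speckle the
  local-maximum test thins the mask and biases its mean upward by roughly
  half the speckle SD; at the speckle levels modeled here the bias is well
  under the tolerance of any downstream check.
- **Anchor values** are means of the *source* frame under the masks,
  reported to 2 decimals; on a zero-noise phantom they equal the
  programmed region brightness exactly.

## The standardization map

With anchors `CenterGray < StandardGray < RimGray`, gray level `X` maps to

- 0 when `X <= CenterGray`;
- `StandardGray · (X − CenterGray)/(StandardGray − CenterGray)` on the
  lower branch;
- `StandardGray + (255 − StandardGray)(X − StandardGray)/(RimGray − StandardGray)`
  on the upper branch;
- 255 when `X > RimGray`.

The printed form of this transformation in its original source is
typographically corrupted; the reading adopted here is the one consistent
with its stated purpose — two linear stretches that pin the anechoic center
at 0, the rim at 255, and fix `StandardGray` — and it makes the map
monotone, continuous, and the identity for anchors `(0, s, 255)`.
`StandardGray` itself is computed as
`(255 − RimGray)(1 + (255 − RimGray)/CenterGray)`, clamped into
`[CenterGray + 1, RimGray − 1]`; because this expression is an
interpretation rather than a verified transcription, it is overridable
(`config$standard_gray`), and `CenterGray = 0` falls back to the
center–rim midpoint with a warning. Values outside the anchor interval
clamp to 0/255, outputs are rounded half-up to integers, and degenerate
anchors (any zero-width segment) are a validation error.

## ROI statistics

`compute_roi_stats()` reports min, max, mean, SD, median and quartiles of
the brightness multiset under the mask. Conventions, fixed and documented:

- **Population SD** (divisor `n`). ROIs have thousands of pixels, so the
  `n` vs `n − 1` distinction is negligible, but a single convention keeps
  oracle tests exact.
- **Quartiles** by linear interpolation between order statistics
  (`quantile()` type 7).
- ROIs need at least 25 pixels (configurable) — below that the SD and
  quartiles are too unstable to be meaningful.
- ROI input is a binary mask or a polygon rasterized over pixel centers
  with the even-odd rule.

## Diagnostics

- The cutoff rule compares inclusively (`>=`) at `T_mean` 65 and `T_SD` 75;
  combinations `either`, `both`, `mean_only`, `sd_only`.
- Confusion-matrix rates are percentages with 95% **Wilson score**
  intervals. The Wilson interval was chosen for its coverage at the small
  non-GIST group sizes involved; confidence intervals are a reporting aid
  here, not a reproduction target. Rates with zero denominators are
  reported as undefined (`NA`), not 0.
- The ROC sweeps integer cutoffs 0–255 with the `>=` rule, AUC by
  trapezoid, optimal cutoff by Youden's `J = sensitivity + specificity − 1`
  with ties broken toward the lower cutoff.
- One-way ANOVA and the pooled-variance two-group t test delegate to
  `stats::oneway.test(var.equal = TRUE)` and `stats::t.test(var.equal =
  TRUE)`. Degenerate inputs the stats functions refuse are given explicit
  conventions: zero between-group variability returns `F = 0, p = 1`; zero
  within-group variance with different means reports a machine-floor
  p-value with a warning.

## What the synthetic data emulate — and what they do not

`generate_phantom()` draws each region's pixels independently from a
Gaussian, clips to \[0, 255\], then rounds. Clipping before rounding biases
moments near the range edges, so programmed values sit well inside the
range wherever moment recovery matters. The default geometry is a 200×200
frame, a radius-14 center disk at the frame center, a 16–24 px rim
annulus at brightness 240, background 120 with speckle SD 8, and a
~2000-pixel tumor ellipse at mean 80 / SD 15 — proportions similar to a
7.5 MHz radial frame.

`generate_cohort()` draws `(T_mean, T_SD)` pairs per lesion from per-group
Gaussians. Defaults are the observed group statistics on standardized
frames — GIST `82.8 ± 22.5` / `83.5 ± 14.4`, leiomyoma `39.8 ± 18.9` /
`54.3 ± 21.7`, schwannoma `47.0 ± 12.0` / `58.3 ± 17.5`, sizes 50/6/9 —
so the simulation reproduces the study conditions at the group level.
Under this model the either-rule's expected sensitivity has the closed form
`1 − Φ((65−82.8)/22.5) · Φ((75−83.5)/14.4) ≈ 0.94`, which the simulation
checks converge to.

Deliberate simplifications:

- **No physical ultrasound model**: no point-spread function, attenuation,
  log compression, or correlated speckle. Gaussian per-pixel noise keeps
  programmed moments interpretable; real speckle is spatially correlated
  and non-Gaussian.
- **Independence of `T_mean` and `T_SD` within a lesion**: only marginal
  group statistics are available, so the joint distribution is
  unidentifiable; independence is assumed. Cohort-level test results
  validate the marginal behavior only.
- Phantom scope geometry is concentric circles; extraction, however, only
  assumes a dark compact object near the configured transducer position,
  not exact centering.

Consequently, green tests demonstrate correctness of the arithmetic and
the group-level statistical behavior under the stated model — not
diagnostic performance on real patient frames.

## Problem sizes and numerical tolerances in the test-suite

The suite checks oracle equivalence on 200 random 32×32 rasters
(labeling), exhaustive 256-threshold scans (Otsu), and 100 random ROIs
(statistics), all exact. Stochastic checks use 5000 lesions per class for
rule sensitivity (tolerance ±2 percentage points around the closed form),
1000 replicates at the study's 50/6/9 group sizes (±4 points), and 200
replicates for the ANOVA rejection rate — sizes chosen so Monte-Carlo error
is a fraction of each tolerance. Phantom-based recovery tests demand the
programmed tumor moments back within ±2 brightness units end to end.

## Known limitations

- The rim-mask thinning bias under heavy speckle (above) grows with
  speckle SD; frames far noisier than the modeled speckle would need a
  larger `radial_tol` or a plateau-aware rim criterion.
- Only single-frequency frames are modeled; no multi-frequency
  harmonization is attempted.
- Automatic tumor segmentation is out of scope by design: the ROI is an
  expert-drawn input.
- Malignancy-risk prediction within GISTs is not modeled; simulated benign
  and malignant GIST groups (means 88.2 vs 82.1, SDs ~22) are
  statistically indistinguishable, matching the two-group comparison the
  package exposes for that sub-analysis.
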
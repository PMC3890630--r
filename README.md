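# eusbright

Quantitative brightness analysis of endoscopic ultrasonography (EUS) frames
for gastric mesenchymal tumors.

## The problem

Gastric mesenchymal tumors — gastrointestinal stromal tumors (GISTs),
leiomyomas and schwannomas — look similar on EUS, and visual judgments of
echogenicity and heterogeneity suffer from poor interobserver agreement.
GISTs are potentially malignant and need resection or tissue sampling, so an
objective, reproducible discriminator matters clinically.

This package implements a digital image analysis that makes those judgments
numeric. An EUS frame is an 8-bit grayscale raster (0 = black, 255 = white),
but its gray scale shifts with the gain/contrast settings of each
examination. Two structures with near-constant appearance anchor a
standardization: the **anechoic center** of the scope (dark transducer core,
brightness `CenterGray`) and its **hyperechoic rim** (bright ring,
`RimGray`). After standardization, a manually delineated tumor region of
interest (ROI) is summarized by

- `T_mean` — mean ROI brightness (echogenicity), and
- `T_SD` — ROI brightness standard deviation (heterogeneity),

and a lesion is predicted to be a GIST when `T_mean >= 65` **or**
`T_SD >= 75` (cutoffs chosen by ROC/Youden optimization).

## The method

1. **Anchor extraction** — histogram smoothing (equalization), Sobel
   gradients, iterative edge linking (neighbors link when their gradient
   magnitudes differ by at most `Th = 130`), binarization (Otsu),
   grassfire connected-component labeling, and morphological noise removal
   (area and circularity filters). The anechoic center is the surviving
   dark component nearest the transducer position; the rim is the adjacent
   ring of radially locally maximal bright pixels.
2. **Standardization** — a monotone piecewise-linear remap with fixed point
   `StandardGray = (255 − RimGray)(1 + (255 − RimGray)/CenterGray)`:

   ```
   X ≤ CenterGray                 →  0
   CenterGray < X ≤ StandardGray  →  StandardGray (X − CenterGray)/(StandardGray − CenterGray)
   StandardGray < X ≤ RimGray     →  StandardGray + (255 − StandardGray)(X − StandardGray)/(RimGray − StandardGray)
   X > RimGray                    →  255
   ```

3. **ROI statistics** — min, max, `T_mean`, `T_SD` (population SD), median
   and quartiles of the ROI brightness values.
4. **Diagnostics** — cutoff-rule classification; sensitivity, specificity,
   PPV, NPV and accuracy with 95% Wilson score intervals; empirical ROC
   over integer cutoffs with trapezoidal AUC and Youden-optimal cutoff;
   one-way ANOVA of `T_mean`/`T_SD` across the three histology groups.

No patient images ship with the package. A synthetic-data module generates
(a) phantom frames with the scope geometry and programmed region brightness
and (b) lesion cohorts drawn from per-group Gaussians, so the whole chain is
testable against known ground truth.

## Worked example

```r
library(eusbright)
ph <- generate_phantom(phantom_spec(seed = 8))   # speckled phantom frame
anchors <- extract_scope_anchors(ph$image)
anchors
#> Scope brightness anchors
#>   center (anechoic):   10.59
#>   standard:            22.89
#>   rim (hyperechoic):   243.85
#>   center mask: 613 px; rim mask: 588 px

std <- standardize_image(ph$image, anchors)
stats <- compute_roi_stats(std, ph$truth$tumor_mask)
stats
#> ROI brightness statistics (n = 2081 pixels)
#>   T_mean (echogenicity):  83.06
#>   T_SD (heterogeneity):   15.67
#>   min/median/max:         37 / 83 / 141
#>   quartiles (Q1, Q3):     72, 93

classify(data.frame(t_mean = stats$mean, t_sd = stats$sd), eus_rule())
#>   t_mean  t_sd predicted_label
#> 1  83.06 15.67            GIST
```

The phantom's tumor was programmed at mean 80 / SD 15 with near-identity
anchors, and the pipeline recovers `T_mean = 83.06`, `T_SD = 15.67` after
standardization (the extracted anchors are slightly off 0/255, which
stretches the scale by a few percent); the lesion is correctly flagged as a
GIST because `T_mean >= 65`.

A simulated 65-lesion cohort (50 GIST, 6 leiomyoma, 9 schwannoma; group
Gaussians as observed on standardized frames) reproduces the group-level
behavior of the rule:

```r
sim <- run_cohort_simulation(list(cohort = list(seed = 42)))
sim$metrics
#> Confusion counts: TP=48 FP=2 FN=2 TN=13 (n=65)
#>   sensitivity   96.0% (95% CI 86.5-98.9)
#>   specificity   86.7% (95% CI 62.1-96.3)
#>   ...
sim$roc_t_mean
#> ROC analysis of t_mean (GIST vs non-GIST)
#>   AUC (trapezoid):       0.883
#>   Youden-optimal cutoff: 63 (J = 0.707)
```

The Youden-optimal `T_mean` cutoff on this simulated cohort (63) lands next
to the fixed rule cutoff of 65, and one-way ANOVA of `T_mean` across the
three groups gives `F = 13.7, p = 1.2e-05`.

## Package layout

- `R/synth.R` — phantom frames and Gaussian lesion cohorts with truth
- `R/preprocess.R` — equalization, Sobel, edge linking, Otsu, grassfire
  labeling, noise removal
- `R/anchors.R`, `R/standardize.R` — anchor extraction and the gray-level
  remap
- `R/roistats.R` — ROI brightness statistics and histogram
- `R/diagnostics.R` — cutoff rule, confusion metrics, ROC, ANOVA
- `R/pipeline.R` — end-to-end runs over images or simulated cohorts
- `vignettes/echogenicity-standardization.Rmd` — the methods vignette
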
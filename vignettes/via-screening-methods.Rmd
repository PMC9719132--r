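---
title: "Methods: automated VIA screening from cervix photographs"
author: "viascreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated VIA screening from cervix photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viascreen)
```

## The screening problem

Visual inspection with acetic acid (VIA) screens for cervical precancer by
observing whether cervical epithelium turns white ("acetowhite") about a
minute after 3–5% acetic acid is applied. The readout is subjective and
depends heavily on examiner experience, which motivates automating it from a
smartphone photograph of the cervix taken after acid application. viascreen
implements that automation as a classical feature-engineering pipeline:

1. **Pre-processing** — resize to a 200 × 200 working resolution, then detect
   and inpaint specular reflections (the saturated glints on the wet mucosa).
2. **ROI detection** — isolate the cervix disk from speculum and vaginal-wall
   background with a Gaussian mixture model on the Ra space, and zoom the
   detected region back to 200 × 200.
3. **Feature extraction** — a fixed 75-feature colour and texture panel
   computed only over the detected ROI.
4. **Selection** — multicollinearity pruning at |r| > 0.9 and z-score
   normalization, fitted on training data only.
5. **Classification** — 25-fold cross-validated selection among nine
   classifier families under PrecisionAtRecall(0.8), final training with a
   decision threshold of 0.29 on the positive-class score.

Because the underlying clinical images are not public, the package ships a
seeded synthetic scene generator that emulates the geometry the pipeline
exploits; every stage is tested against ground truth the generator provides.

## Specular reflection removal

Highlights on the wet cervix are nearly white and bright: *low* HSV
saturation, *high* green intensity, *high* CIE-Lab lightness. Three channels —
S inverted, G, and L — are each min-max normalized to [0, 1] and averaged
into a single feature image, which is then passed through a 3 × 3
standard-deviation filter (population SD, edge replication) and min-max
normalized again. Flat regions, however bright, give no response; highlight
*boundaries* respond strongly.

Detection thresholds this response at 0.5 (configurable), dilates by one
pixel, and fills fully enclosed holes — the flat saturated core of a larger
highlight produces no boundary response of its own, but its rim surrounds it,
so hole filling recovers the interior. Masked pixels are then replaced by
iterative boundary-mean inpainting: each pass fills mask pixels adjacent to
known pixels with the mean of their known 8-neighbours, marching inwards.
Everything outside the mask is returned bit-identically.

Two degenerate cases are pinned by the normalization guard: a perfectly
uniform image (including an entirely saturated white one) has no contrast,
yields an all-zero feature image, and therefore an empty mask — no contrast
means no detection.

Colour conventions are pinned for reproducibility: sRGB input, HSV per the
standard hexcone model with S in [0, 1], CIE-Lab under D65 with L in
[0, 100].

## ROI detection on the Ra space

Each pixel is described by the pair (R, a): R is its Euclidean distance from
the frame centre `((H−1)/2, (W−1)/2)` in pixels and a is its CIE-Lab a*
value. The cervix is central (small R) and pink-red (large a*), the surround
is peripheral and darker/less chromatic, so two spherical Gaussians separate
them well. Design choices the method description leaves open, pinned here:

* **Two mixture components** (cervix vs everything else): the ROI of
  interest is a single central blob.
* **Joint z-scoring of R and a before fitting** — R spans roughly [0, 140]
  on a 200 × 200 frame while a* spans about [−60, 60]; spherical covariance
  is only meaningful on comparable scales.
* **K-means initialization** (10 restarts, seeded) followed by EM with
  spherical covariances; the EM runs on a deterministic subsample of at most
  20 000 pixels and all pixels are then assigned from the fitted parameters.
* **Component choice**: smallest mean R, ties broken by larger mean a*.
* The "spherical ROI" is interpreted in feature space, not forced to a
  geometric circle; the binary mask is cleaned by keeping the largest
  connected component and filling holes, which also recovers specular or
  acetowhite pixels misassigned inside the disk.

The crop stage takes the tight bounding box of the mask, pads it by 5% of
the box size per side, clips to the frame, and resizes to 200 × 200
(bilinear for the image, nearest-neighbour for the mask, which is carried
forward so feature extraction stays ROI-masked). Resizing uses a
centre-aligned bilinear convention under which a same-size resize is exactly
the identity.

If segmentation fails entirely, prediction falls back to a whole-image ROI
with a warning rather than refusing to answer.

## The 75-feature panel

All features are computed strictly inside the ROI mask.

* **Colour (12)** — mean and population SD of R, G, B, G/(R+1), B/(R+1) and
  HSV value V. The +1 in the ratio denominators guards against division by
  zero on 8-bit values; the guard is part of the feature definition.
* **GLCM (28)** — symmetric normalized co-occurrence matrices at distance 1
  in the four standard directions, pairs restricted to both-pixels-in-mask;
  14 Haralick statistics per direction (energy, contrast, correlation,
  variance, homogeneity, sum average/variance/entropy, entropy, difference
  variance/entropy, the two information measures of correlation, and the
  maximal correlation coefficient), each summarised by its mean and its
  range over the four directions. Natural logarithms, 0 log 0 = 0;
  correlation and MCC are defined as 0 when fewer than two gray levels are
  occupied.
* **NGTDM (5)** — the Amadasun–King coarseness, contrast, busyness,
  complexity and strength, with 3 × 3 neighbourhoods restricted to masked
  pixels. When a region holds a single gray level the sum of gray-tone
  differences is zero; coarseness is then reported at its documented cap of
  10^6 and contrast, busyness, complexity and strength as 0.
* **GLSZM (14)** — zones are 8-connected components of equal quantized gray
  level. The statistic set is pinned to: small/large zone emphasis,
  gray-level non-uniformity and its normalized form, zone-size
  non-uniformity, zone percentage, low/high gray-level zone emphasis, the
  four small/large × low/high combinations, and gray-level and zone-size
  variances. (Several closely related 14-statistic readings exist; this one
  is fixed and documented rather than claimed to match any other tool
  exactly.)
* **DWT (6)** — a single-level 2-D wavelet transform (Haar by default, db2
  available) of the grayscale crop with out-of-mask pixels set to the masked
  mean; mean and population SD of absolute coefficients in the LH, HL and HH
  detail subbands.
* **LBP (10)** — uniform local binary patterns with 8 integer-ring
  neighbours at radius 1 and the standard neighbour ≥ centre sign
  convention: nine uniform bins indexed by the number of ones plus one
  non-uniform bin, normalized to sum to 1. Only pixels whose full
  8-neighbourhood lies inside the mask contribute. Under the ≥ convention a
  constant region lands in the all-ones uniform bin.

Grayscale is Rec. 601 luma (0.299 R + 0.587 G + 0.114 B) quantized to 16
equal-width levels over the masked range — a common radiomics default that
keeps the exhaustive test oracles tractable. Every texture family is
verified in the test suite against naive loop-based reference
implementations on small rasters.

A mask must contain at least 64 pixels; below that the panel is refused
rather than silently returning unstable statistics.

## Selection and normalization

Zero-variance features are dropped first. The absolute Pearson correlation
matrix of the training rows is then traversed along the upper triangle in
panel order; whenever |r| exceeds 0.9 and both features are still alive, the
later-ordered feature is dropped and its retained partner recorded. Keeping
the earlier feature is a determinism choice — the threshold is specified,
the drop rule is not. Z-score parameters (mean, population SD) are fitted on
the kept features. Fit and apply are separate operations, so test data can
never leak into the transform; the fitted state serializes to JSON for
reuse at prediction time.

Raising the threshold can only keep more features; the suite asserts this
monotonicity over {0.5, 0.7, 0.9, 1.0}.

## Classification and evaluation

Nine classifier families sit behind a thin adapter (id → fit/score), all
seeded and single-threaded, with library defaults and no hyperparameter
search: gradient boosting and histogram ("light") gradient boosting via
xgboost, logistic regression via `glm`, random forest, extra trees via
ranger, Gaussian naive Bayes, AdaBoost.M1 over depth-1 stumps, k-nearest
neighbours (k = 5), and a CART decision tree.

**PrecisionAtRecall(0.8)** is the model-selection objective: over all
thresholds in the distinct score set (plus −∞), the best precision subject
to recall ≥ 0.8. Cross-validation is stratified — with 26 positives in 134
rows, unstratified 25-fold splits can produce folds without a positive,
leaving recall undefined — and the selection pipeline is re-fitted inside
every training fold. Ranking ties are broken by registry order so the
selected algorithm is reproducible.

Prediction thresholds the positive-class score at 0.29 (score ≥ threshold ⇒
positive). Evaluation reports the confusion matrix, sensitivity,
specificity, accuracy and precision (NA when a defining denominator is
zero, never silently 0), the threshold-swept ROC, the trapezoid-rule AUC
(identical to the normalized Mann–Whitney U statistic, an identity the
suite checks to 1e-12), and a 95% percentile bootstrap CI for the AUC
(2000 stratified resamples, seeded, clipped to [0, 1] — the CI method is a
package decision; the original report gives none).

## The synthetic scene generator

`generatorConfig()` defines the study conditions the tests run under:
400 × 400 scenes; a pink cervix disk (mean RGB 205/120/130) of radius
0.28–0.38 of the frame on a darker low-chroma surround (70/50/55); centre
jitter up to 5% per axis; Gaussian pixel noise of SD 8 clipped to [0, 255];
3–8 saturated specular highlights of radius 2–6 px (cores ≥ 250 in every
channel, 1 px soft rim, painted after the noise so saturation is exact);
and, in positive scenes, one matte whitish lesion (235/205/215) rendered as
a rotated ellipse with Gaussian alpha falloff whose semi-axes are 0.25–0.45
of the cervix radius. The soft lesion edge matters: it makes the patch
visible to the texture families (GLCM, GLSZM, wavelet), not just to colour
means. Prevalence defaults to 0.181, matching a 36/199 positive fraction;
`round(n × prevalence)` scenes are positive. Scene k's seed is derived from
the master seed by a counter, so a scene is reproducible regardless of batch
size. `lesionContrast` scales the lesion towards invisibility and is the
negative-control dial: at 0 the generated classes are exchangeable and the
pipeline must fall to chance.

What the generator deliberately does **not** emulate: speculum and vaginal
wall geometry beyond a darker annulus, illumination gradients, colour casts
between devices, mucus/blood artefacts, squamocolumnar-junction structure,
and before/after acid image pairs (the classifier consumes the
post-application image only — the corresponding open design question is
resolved here as single-image classification). Passing the synthetic
recovery tests therefore demonstrates that the implementation is faithful
and the pipeline can recover a planted signal under realistic noise; it does
not certify clinical performance, and the dataset-level numbers of the
original study (per-algorithm cross-validation scores, the particular 31
retained features, AUC on its private test set) are properties of data this
package cannot access.

## Problem sizes used by the checks

The synthetic-recovery experiments mirror the study's sample sizes: 199
scenes at prevalence 0.181 split 134/65 with the study's class balance
(26 + 10 positives), 25 CV folds, and a 200-scene negative control. Unit
tests run the same code on smaller frames (120 × 120 scenes, 64 × 64
working resolution) purely to keep feedback fast; the acceptance checks use
the full-size defaults.

## Known limitations

* The specular-removal and ROI stages are described only loosely by the
  method text; thresholds, the channel-combination rule, the mixture size
  and the component-selection rule here are pinned, configurable decisions,
  not claims of parity with the original system.
* The exact 14-statistic GLSZM set, the quantization depth and the wavelet
  are likewise pinned choices among several defensible readings.
* Inpainting is boundary-mean diffusion — adequate for small glints, not a
  general-purpose restoration method.
* The generator's colour distributions are stylised; models trained on
  synthetic scenes should not be applied to photographs.
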
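---
title: "Spectrum-image fusion for two-range hyperspectral classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrum-image fusion for two-range hyperspectral classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsifuse)
```

## The problem

Line-scan hyperspectral cameras image sliced plant material (for example,
dried medicinal rhizome slices) in two complementary ranges: a
visible/near-infrared (VNIR) camera around 435–1042 nm and a short-wave
infrared (SWIR) camera around 898–1751 nm. Each acquisition is a data-cube
of shape rows × cols × bands. The classification task — assigning each
slice to its geographical origin or quality class — can draw on two kinds of
information per slice: the *mean reflectance spectrum* of its pixels, and
the *spatial texture* of its gray-level images. Neither is complete: the
spectrum summarizes chemistry but discards spatial structure; texture
statistics capture surface micro-structure but ignore band shapes.
`hsifuse` implements a feature-level fusion scheme that concatenates
auto-scaled spectral and textural feature blocks across the two camera
ranges along three fusion dimensions (across ranges, across modalities,
and all four blocks), and classifies the fused features with PLS-DA or an
RBF SVM.

## Pipeline overview

1. **Calibration.** Raw counts are converted to reflectance with white
   and dark references, `(raw − dark)/(white − dark)`, clipped at zero;
   pixels with `white == dark` are flagged dead and set to zero.
2. **Segmentation.** A contrast image (band of highest spatial mean minus
   band of lowest spatial mean) is thresholded with Otsu's criterion on a
   256-bin histogram; connected components above a minimum area become
   per-slice ROIs, ordered top-to-bottom then left-to-right.
3. **Spectral preprocessing.** SNV, MSC, Savitzky–Golay smoothing
   (order-3 polynomial; 9/13/17/21-point windows) and SG first/second
   derivatives. The default recipe is the second derivative with a
   17-point window, which removes additive and linear multiplicative
   baseline components.
4. **Band selection.** The successive projections algorithm (SPA) builds
   a candidate chain from every start band by repeatedly picking the band
   with the largest norm after projection onto the orthogonal complement
   of the chosen bands; chain prefixes are scored by stratified 5-fold CV
   of a least-squares one-hot classifier and the lowest-error subset wins.
5. **Textures.** At the selected wavelengths only, each ROI is min–max
   quantized to L = 16 gray levels and summarized by GLCM statistics
   (contrast, dissimilarity, homogeneity, energy, correlation × 4 angles
   = 20 values) and GLRLM statistics (7 run-length measures, averaged
   over the 4 angles).
6. **Fusion and models.** Blocks are auto-scaled on calibration rows and
   concatenated; PLS-DA (NIPALS on the centered one-hot indicator) or an
   RBF SVM with a decade grid over C and g classifies the result;
   performance is reported as calibration/prediction accuracy, a
   confusion matrix, and one-vs-rest trapezoidal macro-AUC, with
   ten-times-five-fold stratified cross-validation.
7. **Maps.** Cubes are block-averaged to a common grid (the native
   512 × 1200 and 640 × 1500 frames reach 128 × 300 with 4 × 4 and 5 × 5
   blocks) and a full-band PLS-DA model labels every foreground pixel,
   rendered in primary colors.

## Design choices on genuinely open points

Several details are not fixed by common practice; the package settles
them as follows.

* **Contrast image.** "Highest/lowest intensity" is read as band-level
  selection by spatial mean; a per-pixel spectral max−min variant is
  available behind `perPixel = TRUE`. Band-level is the default because
  it cancels shared illumination structure while remaining a linear
  operation on two bands.
* **Texture counts.** GLCM is reported per angle (20 values) while GLRLM
  is averaged over angles (7 values); this asymmetry follows the
  canonical feature counts for the two families.
* **Quantization.** Gray levels default to L = 16: coarse enough that
  run-length statistics are stable on ROIs of a few hundred pixels, fine
  enough that GLCM correlation retains contrast. The paper-style deep
  texture analysis is not sensitive to this choice in our experiments.
* **SPA scoring.** The subset scorer is a least-squares one-hot linear
  classifier: fast, deterministic, and close in spirit to PLS-DA at full
  rank (at full rank the two coincide exactly). Candidate sizes default
  to 2–30 bands (2–10 in the orchestrated pipeline, where the exhaustive
  start-band search makes larger caps expensive).
* **Derivatives** are taken per band index, not per nm; the grids are
  nearly uniform, and a `perNm` flag rescales when needed.
* **MSC reference** is the mean calibration spectrum, reused unchanged
  for prediction samples, so no test-set statistics enter the operator.
* **PLS-DA latent count** candidates are 1–10 (treating "under 10"
  inclusively); `plsdaSelectLatent()` picks by repeated CV. NIPALS stops
  at a relative tolerance of 1e-10 with a 500-iteration default budget;
  the orchestrated pipeline raises the budget to 5000 because
  weak-signal folds (eigenvalue near-ties) converge slowly but correctly.
* **Split rounding.** The stratified 2:1 split takes `floor(2n/3)` of
  each class for calibration, reproducing a 149/75 partition for class
  sizes (128, 48, 48).
* **Multiclass ROC** is one-vs-rest with unweighted macro averaging;
  AUC uses the trapezoidal rule with tied scores grouped.
* **Experiment grid.** The consolidated grid crosses
  {VNIR, SWIR, VNIR+SWIR} × {spectra, GLCM, GLRLM, spectrum+image} ×
  {full, SPA bands} for the configured model (24 rows per model).
  Textures are always computed at the SPA wavelengths — extracting them
  at hundreds of bands would be redundant — so image-only rows repeat
  across band sets, and the spectrum+image set pairs spectra with the
  GLRLM block (the stronger image family for fusion).

## The synthetic scene generator

No public data accompany this kind of sliced-material study, so the
package ships a seedable generator (`sceneConfig()`, `generateScene()`)
that emulates the relevant physics and serves as the test bed:

* elliptical slices of `nClasses` classes on a dark background, placed
  without overlap on banded cells so that reading order is unambiguous
  at both camera resolutions (0.16 mm and 0.23 mm pixels);
* class endmembers built as a flat baseline (0.6) minus Gaussian
  absorption bands; two bands (a blue-end absorption at 455 nm and a
  water-like band at 1450 nm) are shared by all classes, as in real plant
  tissue, which is what makes the max-minus-min contrast image separate
  every class from the background;
* per-pixel scatter `(a + b·E(λ))` with `a ~ N(0, 0.002)` and
  `b ~ logN(0, 0.05)`, a unit-mean multiplicative texture field with a
  class-specific spatial correlation length (1 px "fine" vs 6 px
  "coarse"), and i.i.d. band noise (sd 0.001);
* emission as raw counts with matched white/dark references, so
  calibration is exercised end-to-end.

`signalSplit` decides where class information lives: `spectral_only`
(three distinct endmembers, one texture), `texture_only` (one endmember,
three correlation lengths), or `both` — the complementary split in which
classes 1 and 2 share an endmember while classes 1 and 3 share a texture,
so no single block can separate all three classes but their fusion can.
This is the testable analogue of the fusion-benefit ordering that
motivates the method.

The defaults use the real wavelength grids (435–898 nm at 2.6 nm;
900–1601 nm at 1.67 nm) but smaller spatial frames (160 × 120 VNIR,
scaled by the pixel-size ratio for SWIR) and 12 slices per scene; five
scenes give the 60-sample experiments used throughout the tests and the
acceptance script. Map-geometry checks use the full 512 × 1200 and
640 × 1500 frames with a thin spectral axis.

What the generator does *not* emulate: real phytochemical band
assignments, camera-specific radiometric response, spatial co-registration
artefacts between ranges, and touching slices. Passing tests therefore
demonstrate the pipeline's correctness and the fusion mechanism, not
field performance on any particular crop.

The noise scales deserve one remark: the per-pixel multiplicative scatter
(5%) dominates the additive terms (≤0.2%) by design. Multiplicative
white noise is removed by the per-ROI min–max quantization equally for
every class, whereas additive noise enters texture statistics scaled by
1/E(λ) — a class-dependent quantity — which would leak spectral identity
into the texture block and break the `spectral_only` contract ("texture
statistics identical across classes by construction").

## Numerical details

* Otsu's threshold is computed from cumulative sums over a 256-bin
  histogram; the returned threshold is the upper edge of the best
  background bin, and foreground is strictly above it. Constant images
  are rejected.
* Connected components are labelled through an adjacency graph over
  foreground pixels (4- or 8-connectivity); components touching the
  border are kept; ROI ordering depends only on bounding-box origins.
* SPA deflates residuals in place (one Gram–Schmidt step per selection);
  chains truncate when the largest projected norm falls below 1e-12.
  Tie-breaks are always "lowest band index", and subset scoring memoizes
  duplicate candidate subsets.
* The GLCM is symmetric (each ordered pair counted both ways) and
  normalized per angle; correlation is defined as 0 for zero marginal
  variance. GLRLM runs are broken by mask boundaries; pixel conservation
  (Σ j·p(i,j) = in-mask pixel count) holds per angle.
* Zero-variance feature columns are centered but not scaled, and
  flagged; degenerate inputs (constant ROI, empty mask, single-class
  labels) raise errors rather than produce NaNs.
* All randomness (splits, folds, SVM grid folds, scene noise) derives
  from explicit integer seeds; repeated CV re-randomizes folds per
  repeat from offsets of the base seed.

## Problem sizes

The package's own experiments run at 60 samples (five scenes of twelve
slices), 179 VNIR plus 420 SWIR bands, SPA caps of 10 bands per range,
and 10×5 cross-validation; these sizes make the full suite and the
acceptance script comfortable on a single CPU while leaving every code
path exercised end-to-end.

## Known limitations

* VNIR and SWIR samples are matched by reading-order rank (the generator
  additionally verifies the match against its ground truth); physically
  co-registering the two ranges is out of scope.
* Touching slices are not separated (no watershed step).
* SVM class scores for ROC are one-vs-one vote fractions — coarser than
  PLS-DA's continuous responses; ROC analysis is best read from the
  PLS-DA models.
* The SPA phase-3 variable elimination is not implemented.
* Reported chance-level checks are statistical: individual label-permuted
  runs fluctuate around 1/3 within binomial noise.
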
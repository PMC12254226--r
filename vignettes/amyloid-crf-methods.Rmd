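---
title: "Detecting cardiac amyloid on Congo red fluorescence slides: methods and design notes"
author: "amyloidCRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cardiac amyloid on Congo red fluorescence slides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyloidCRF)
```

## The measurement problem

Congo red (CR) is the canonical amyloid stain, classically read as
apple-green birefringence under polarized light -- a modality most slide
scanners cannot digitize. Amyloid-bound CR, however, fluoresces strongly
in the red (Texas Red / TRITC) band, so a fluorescence scanner can capture
the dye signal directly. The catch is tissue autofluorescence: myocardium,
and especially fibrotic or collagen-rich areas, glow in the same emission
band and mimic deposits. The remedy implemented here acquires the same
physical slide through two filter combinations:

* a **TRITC channel** `T` capturing dye fluorescence plus
  autofluorescence, and
* a **scramble channel** `S` (off-dye excitation, same emission) capturing
  autofluorescence alone.

Because both images come from one slide on one stage, they share a pixel
grid, and the deposit signal is the one-sided excess

$$D = \max(T - S,\; 0).$$

Everything common to both channels -- parenchyma, fibrosis, vessels --
cancels; what remains is amyloid. `D` is binarized within the tissue mask,
cleaned of sub-resolution speckle, and measured as the **amyloid burden**

$$\text{burden} = \frac{|\text{deposit pixels}|}{|\text{tissue pixels}|}.$$

The mask transfers to the aligned brightfield image by identity (no
co-registration), where it yields weakly-labelled 256 x 256 tiles for
training a classifier and a per-pixel segmenter that work on brightfield
alone.

## Numerical choices in the segmentation

**Subtraction clips at zero** rather than taking absolute values: pixels
brighter in the scramble channel carry no amyloid evidence.

**Tissue detection** thresholds the pixelwise maximum of the two
fluorescence channels. The maximum, not the scramble channel alone,
because dense deposits locally *suppress* autofluorescence -- on the
scramble channel alone they would appear as holes in the tissue. The
threshold is found hierarchically: a first Otsu pass on the linear
intensities strips bright minority modes (deposits, fibrotic
autofluorescence), then a second Otsu pass in log-intensity below that cut
separates dark background from dim tissue. Fluorescence contrast is
multiplicative, so the background/tissue decision is best made on a log
scale; the second split is accepted only when its two classes are well
separated (standardized mean difference > 3.5), otherwise the histogram
below the first cut is unimodal background and the first cut stands.
Detected tissue is hole-filled and components under `tissueMinObjectPx`
(default 256 px) are dropped. A limitation follows from the method: a
slide that is *all* tissue, with no background at all, has a unimodal
histogram and no threshold is well defined; constant rasters are special-
cased, but near-constant ones remain ill-posed for any Otsu-family rule.

**Binarization of `D`** uses Otsu computed on the in-tissue pixels only
(the background would otherwise dominate the histogram), with a floor of
`minSignal = 0.1` (~26/255) on the resulting threshold: on a deposit-free
slide Otsu has no second mode and would split the noise distribution in
half, and subtraction residue below the floor is indistinguishable from
autofluorescence noise. A `fixed` threshold mode exists for exact
reproducibility across reagent lots. Deposit components under
`minObjectPx = 16` px (~3 um^2 at 0.4415 um/px) are removed -- speckle
suppression that still keeps minimal vascular-scale deposits. All
connected components, everywhere in the package, are 8-connected.

**Annotation transfer** vectorizes the mask with `contourLines` at the 0.5
level of the zero-padded raster, so an axis-aligned filled square of 100
pixels becomes a polygon of area exactly 100 px^2; polygons are written as
GeoJSON in pixel coordinates (x right, y down, 0-based) and rasterize back
by even-odd scanline filling.

## What the synthetic generator emulates

No public slide set accompanies this problem, so the package ships a
generator whose defaults *are* the study conditions used by every test:

* slides of 512 x 512 px at 0.4415 um/px (a 20x scan), tissue covering
  ~80% of the field as a wavy-edged region;
* the four cardiac deposition geometries: **diffuse pericellular** (a
  reticular lattice along simulated myocyte boundaries, built from the
  edges of a Voronoi tessellation with ~14 um cells), **discrete
  pericellular** (a sparse subset of whole lattice edges), **nodular**
  (few large irregular blobs) and **vascular** (annular deposits around
  vessel profiles);
* an intensity model on the 8-bit-equivalent [0, 1] scale: amyloid
  TRITC 0.8 / scramble 0.1; plain tissue 0.15 in both channels; fibrotic
  confounders 0.45 in both; background 0.02; Gaussian pixel noise of
  configurable sd (default 0.01). These values make subtraction *necessary*
  (confounders defeat single-channel thresholding) and *sufficient* (the
  difference is positive exactly on deposits when noise-free);
* brightfield rendering with tissue in eosinophilic pink and deposits in
  salmon -- distinguishable but low-contrast, as brightfield CR is;
* burden control by iterative deposit placement until the achieved burden
  is within 10% relative of the target (an error after 100 placement
  iterations reports an unachievable geometry). Ground-truth fragments
  under 32 px (~6 um^2) are dropped as physically meaningless, which keeps
  every truth component above the segmentation cleanup scale.

Cohorts draw case burdens from a normal distribution with mean 0.15 and sd
0.13 truncated to [0.02, 0.45] -- the burden scale reported for cardiac CR
cohorts (mean ~15%, maximum ~45%) -- and assign EMB/autopsy specimen types
roughly half and half.

What the generator deliberately does **not** emulate: optical blur and
vignetting, stain fading, scanner stitching artifacts, out-of-focus
regions, nuclei and cellular texture in brightfield, and the full
morphological diversity of real deposits. Passing tests therefore
demonstrate the correctness of the pipeline's logic and arithmetic, not
clinical performance on real slides.

## Tiles, weak labels and the learning harness

Tiles are 256 x 256 px (~113 x 113 um at 0.4415 um/px), on a
non-overlapping grid aligned to the slide origin; partial edge tiles and
tiles with under 10% tissue are excluded. A tile is labelled positive when
it contains at least `positiveMinPx = 64` deposit pixels (~0.1% of the
tile): a small nonzero floor that keeps focal deposits positive while
suppressing single-pixel label noise. Both an `original` and a `masked`
(dark background outside the deposit annotation) variant are available.

Cross-validation is **case-level 10-fold nested**: each fold splits the
cases 80/10/10 into train/validation/test, stratified by label with
specimen type as a secondary balancing key; the test blocks rotate so
every case is tested exactly once, and a leakage assertion re-checks every
fold before training. Slide-level calls average the tile probabilities and
call positive on `mean > 0.5` -- a mean of exactly 0.5 is negative, the
strict inequality favouring specificity.

Two permutation nulls are provided, and they are not interchangeable.
Permuting the **case-level** labels (and propagating them to tiles)
preserves the cohort structure, but on a small cohort the resulting
cross-validated score is *pessimistically biased*, not centred at 0.5:
whatever chance majority pairing a fold's model extracts from its
training cases is anti-correlated with the held-out cases, because the
labels were permuted without replacement; and since flipping every label
flips the learned sign *and* the evaluation labels together, the score is
invariant under the flip and the bias does not cancel by symmetry. On
20-case cohorts we observe pooled test AUCs of 0.0-0.5 under this null.
This is a property of cross-validation under finite label permutation
(well known in the permutation-testing literature), not of this
implementation. The chance-level check therefore shuffles labels at the
**tile level**, severing the image-label link entirely, under which the
median fold test AUC concentrates near 0.5.

The built-in networks are deliberately small (the harness is
architecture-agnostic and a model spec injects the backend): a
3-conv-block CNN with global average pooling for tile classification and a
one-stage U-shaped CNN with a skip connection for per-pixel segmentation.
Tiles are block-mean downsampled to 32 x 32 network inputs; color
augmentation (HSV jitter: hue +-0.05, saturation x[0.7, 1.3], value
x[0.8, 1.2] -- CR staining varies strongly between batches) operates on
the network input. Training uses Adam on numerically stable binary
cross-entropy, minibatches of 8, early stopping on validation loss. All
convolution kernels are compiled code with analytically derived backward
passes, verified against finite differences in the test suite; all
randomness flows from a single seed, so fits are bit-reproducible.
Grad-CAM explains classifier calls by pooling the logit gradient over the
final convolutional feature map, rectifying the weighted activation sum
and min-max normalizing to [0, 1]; a constant activation map yields a
defined all-zero heatmap.

Problem sizes used by the tests and the acceptance script -- 20-case
cohorts of 512 x 512 px slides, ~80 tiles, 10 folds, <= 15 epochs -- were
chosen as the smallest sizes at which the properties of interest
(separability, chance-level permutation null, burden recovery) are
cleanly expressed.

## Metric conventions

Confusion-matrix metrics follow their closed forms; any metric with a zero
denominator is `NA` with an explicit undefined flag, never silently zero.
AUC is the rank-based (Mann-Whitney) estimator with midrank ties. IoU and
Dice use the convention that two empty masks score 1.0 (a correct
all-negative prediction is not penalized) with a `bothEmpty` attribute
preserving auditability; `dice = 2*iou/(1+iou)` is enforced as an
invariant. Cohen's kappa uses marginal-product expected agreement and is
undefined when that expectation is 1; kappa on real inter-observer tables
cannot be reproduced from an agreement count alone without the raters'
marginals, so the package tests kappa by property and cross-library
agreement rather than against any single published table. Spearman
correlation delegates to `stats::cor`; quartiles are linear-interpolation
(type 7). Display rounding is 2 decimals; raw values are always retained.

## Known limitations

* The generator's intensity model is piecewise-constant plus noise;
  threshold-based segmentation is therefore easier than on real slides,
  which is the point of the exactness tests but a ceiling on realism.
* Pyramidal/proprietary WSI formats are out of scope; rasters are
  full-resolution TIFF/PNG.
* The built-in networks are desk-scale reference implementations; users
  with GPUs and large cohorts will want to plug a heavier backend into the
  same harness via the model spec.
* Unimodal-histogram slides (no background in the field) make tissue
  detection ill-posed, as discussed above.
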
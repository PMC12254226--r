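# amyloidCRF

Detection and quantification of cardiac amyloid on Congo red fluorescence
whole-slide images, plus the downstream learning experiments that such
annotations enable.

## The problem

Cardiac amyloidosis is diagnosed histologically with Congo red, classically
read as apple-green birefringence under polarized light — a modality most
slide scanners cannot capture. Amyloid-bound Congo red, however, fluoresces
strongly in the Texas Red (TRITC) band. The obstacle to using that signal
directly is tissue autofluorescence: myocardium and especially fibrotic
areas glow in the same band and mimic deposits.

This package implements the two-filter subtraction approach. The same
physical slide is acquired through a TRITC filter (dye + autofluorescence,
image `T`) and a "scramble" filter (autofluorescence only, image `S`). The
deposit signal is the one-sided excess

```
D = max(T − S, 0)
```

which is binarized within the detected tissue (Otsu within tissue, small
components removed), measured as the **amyloid burden**

```
burden = deposit area / tissue area
```

and transferred by identity onto the aligned brightfield image as GeoJSON
polygon annotations — no co-registration, because all channels share one
pixel grid. From the annotated brightfield image the package extracts
256 × 256 px tiles (~113 × 113 µm at 0.4415 µm/px) with weak labels, and
provides case-level 10-fold nested cross-validation of a small CNN tile
classifier (with Grad-CAM explainability) and a per-pixel segmenter, with
slide-level calls by mean tile probability at a strict 0.5 threshold.

A synthetic slide generator with exact ground truth (four cardiac
deposition geometries: diffuse/discrete pericellular, nodular, vascular;
fibrosis-like confounders bright in both channels) makes the whole pipeline
testable without patient data. Who this is for: pathology image-analysis
developers who need a reference implementation of fluorescence-subtraction
morphometry and a leakage-safe evaluation harness.

## Worked example

```r
library(amyloidCRF)

sl <- generateSlide(synthSpec(targetBurden = 0.15,
                              pattern = "diffuse_pericellular",
                              noiseSd = 0, seed = 7))
seg <- segmentSlide(sl)
seg$morphometry
#> Morphometry: burden 0.1502 (31532 / 209899 px), 48 components
iou(seg$amyloid, truthAmyloid(sl))
#> [1] 1
```

The slide was asked to carry a 15% amyloid burden; subtraction segmentation
recovers the deposit mask exactly on a noise-free slide (IoU 1) and the
measured burden matches the generated truth. The confusion-matrix helper
reproduces standard slide-level metrics from counts:

```r
classificationMetrics(confusionMatrix(25, 10, 5, 3))
#> MetricReport (n = 43 ):
#>   accuracy = 0.81, sensitivity = 0.89, specificity = 0.67,
#>   precision = 0.83, npv = 0.77, f1 = 0.86
```

A full pipeline run (synthetic cohort → segmentation → tiles → nested CV →
summary) is available both as functions (`cmdSynth`, `cmdSegment`,
`cmdTile`, `cmdCV`, `cmdReport`) and as a thin command-line wrapper:

```sh
Rscript inst/scripts/amyloidcrf.R all --seed 5 --outdir runs/demo
```

## Layout

- `R/`, `src/` — implementation (S4 data classes; compiled conv kernels)
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/amyloid-crf-methods.Rmd` — the model, its assumptions, and
  every numerical design choice
- `inst/scripts/amyloidcrf.R` — command-line pipeline wrapper
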
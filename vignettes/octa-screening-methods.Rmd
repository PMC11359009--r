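---
title: "Methods: OCT-A feature extraction and SVM screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OCT-A feature extraction and SVM screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`octascreen` implements a fixed-pipeline, feature-based approach to
screening for cognitive impairment from OCT angiography: a handful of
interpretable vascular and structural measurements per eye, followed by
small-sample kernel SVMs. This vignette records the model, the tunable
parameters, the synthetic study conditions, and the numerical decisions a
maintainer would otherwise have to reverse-engineer.

## Image model and conventions

All images are numeric matrices of intensities in [0, 255]. Rows run top
to bottom, columns left to right, both 1-based; `img[j, k]` is scan row
`j`, column `k`, and exported coordinates are `(row, col)` pairs in this
convention. Colour inputs collapse to Rec. 601 luminance on load. The
moment sums below run from 1 to the image extents, matching this indexing.

Binarisation is always `pixel >= threshold -> 1`. The tie direction is not
physically meaningful but is fixed for determinism; every mask operation
in the package inherits it.

## En-face (axial) features

**FAZ segmentation.** The angiogram is inverted (avascular tissue becomes
bright), thresholded, and cleaned by opening then closing with disc
elements. Opening removes the thin bright corridors between capillaries;
closing repairs small holes left by noise. Among the surviving 8-connected
components, the one with centroid nearest the image centre is the FAZ
(scans are fovea-centred); its interior holes are filled. If no component
has its centroid inside the central third of the image, the scan is
rejected with a `FAZ not found` error rather than silently measuring a
non-foveal blob.

Key parameters, at the nominal 600 × 600 px resolution:

| parameter | default | units | rationale |
|---|---|---|---|
| `vessel_threshold` | 48 | intensity | device-calibrated vessel/background cut |
| `faz_threshold` | 207 | intensity (on negative) | complement `255 - 48`, so the FAZ and vessel masks partition the intensity axis consistently; the FAZ-side cut is otherwise unconstrained and stays configurable |
| `rvda_threshold` | 178 | intensity (on negative) | device-calibrated cut for locally vessel-poor tissue |
| `open_radius_px`, `close_radius_px` | 5 | px | must exceed half the inter-capillary gap (~10 px at this resolution) without eroding a FAZ of radius >= 30 px |
| `rvda_open_radius_px` | 3 | px | removes speckle below capillary spacing while keeping extended avascular area |

**Moments.** For a binary mask with `J` rows and `K` columns,
`M(m,n) = (1/(J^m K^n)) * sum_x sum_y x^m y^n F(x,y)`. `M(0,0)` is the
pixel count; the centroid de-normalises the first-order ratios back to
pixels: `(J M(1,0)/M(0,0), K M(0,1)/M(0,0))`. The boundary is the mask
minus its erosion by a radius-1 disc, so each boundary pixel has a
background 8-neighbour; the FAZ average radius is the unweighted mean
Euclidean boundary-to-centroid distance over *all* boundary pixels
(sampling would be faster but nondeterministic in effect).

**Sector grid.** The five-zone grid uses one inner radius (the FAZ mean
radius) and one outer radius (three times the inner): zone 1 is the
central disc; zones 2–5 are the annulus cut by the two ±45° diagonals
into superior, nasal, inferior and temporal quadrants. This is the
minimal ETDRS-like geometry consistent with a single radius pair; the
geometry is isolated in `build_sector_zones()` so an alternative grid can
be swapped in without touching density computation. Pixels on a diagonal
tie are assigned deterministically (superior first, then inferior, then
nasal). A zone fully clipped by the image border raises an error naming
the zone, rather than returning a 0/0 density.

**RVDA.** Computed over the whole cropped image including the FAZ — the
avascular zone genuinely is vessel-poor area; `rvda_exclude_faz = TRUE`
removes the FAZ disc from numerator and denominator for sensitivity
analyses.

**Range-filter histogram.** The filter output at each pixel is max − min
over an odd window (default 3 × 3) with replicate borders, which never
invents intensities absent from the image. On the 256-bin histogram, the
peak location is FC (ties broken to the smallest intensity) and the FWHM
is `x_half2 − x_half1`, where `x_half1` is the first bin at or below FC
with count strictly above half the peak and `x_half2` the first bin above
FC with count strictly below half. The two conditions are deliberately
asymmetric — that is how the procedure is defined for this pipeline — so
a single-spike histogram has FWHM 1. When the count never falls below
half-peak to the right, `x_half2` falls back to 255 and the result is
flagged (`x_half2_fallback`); flat histograms therefore return FC 0 and
FWHM 255 rather than erroring.

## B-scan thickness

The B-scan is thresholded (Otsu by default — B-scan brightness varies
more across devices than en-face brightness; any numeric threshold can be
forced), cleaned, and the background is labelled. The background
component above the retina is selected (largest area; ties go to the
earliest component in row-major order), the per-column boundary row is
the zone's lowest background pixel, and the foveal pit is the extremal
boundary column. Because a smooth pit rasterises to a plateau of equally
deep columns, ties resolve to the **median** tied column: the smallest-
index rule would bias the landmark toward the plateau edge by up to half
the plateau width, while the median is unbiased for symmetric pits. A
perfectly flat boundary consequently returns the middle column.

Thickness is measured on the *grayscale* depth profile at that column
(binarising first would discard the gradual transitions the landmarks key
on), smoothed by a width-3 moving average (width 1 disables it; the raw
crossing rule is brittle against single-pixel noise). The starting point
is the first rise from below `start_threshold` (48) to at or above it;
after the profile falls back below that level, the ending point is the
next rise past `rise_threshold` (48, separately configurable since the
deeper band may be dimmer). Both landmark shifts induced by the smoothing
are equal and cancel in the difference. Missing transitions raise
distinct `no retinal surface` / `no deep band` errors. `pixel_scale_mm`
defaults to 0.05 mm/px (30 mm over 600 px, the device-report convention
for these scans); it is a pure output scaling and never enters the
landmark search.

## Classifier and evaluation

Features are z-scored with training-set parameters; a soft-margin SVM
(`C = 1` on the standardised scale) is fitted per task, feature subset
(one or two features) and kernel. RBF-family inverse widths default to
`1/d` after standardisation; the polynomial kernel is quadratic. The
normal class is the positive class throughout — with a roughly 4:1
normal-to-disease imbalance, positive counts on the hundred scale are
only consistent with that mapping — and decision values are oriented so
positive means normal.

Reported metrics follow the pipeline's published definitions exactly:
accuracy `(TP+TN)/n`, specificity `TN/(FP+TN)`, sensitivity `TP/(TP+FP)`
(this is the positive predictive value; the conventional sensitivity
`TP/(TP+FN)` is emitted alongside as `sensitivity_canonical` to prevent
silent confusion), recall `TP/(TP+FN)`. Any metric with a zero
denominator is `NA`, never 0. ROC curves sweep the decision-value
threshold over all observed scores, tied scores advance both axes at
once, and AUC is the trapezoid area.

No evaluation protocol is canonical for a dataset this size, so
`evaluate()` offers both resubstitution (the optimistic, training-set
view) and stratified k-fold cross-validation (default `k = 5`,
fold-assignment seed 1317) with per-fold refitting and pooled confusion
counts; reporting both is the honest default. `search_models()` scans the
five single features and, by default, the four pairs of mean vessel
density with each other feature (`all_pairs = TRUE` gives all ten), keeps
each cell's best kernel by accuracy (ties: higher AUC, then kernel name),
and appends an always-normal baseline row whose accuracy equals the
normal prevalence — the yardstick any imbalanced-cohort result must beat.
Three-class classification is deliberately out of scope; the MCI/AD
contrast is handled as two binary tasks plus a combined normal-vs-(MCI+AD)
task.

## Synthetic study conditions

The phantom generator exists to make every extractor testable with known
ground truth; it emulates geometry, not physics.

*En-face phantoms* draw parallel wavy vessel strokes with an 8-px spatial
period, so the inter-vessel gap `8(1 - coverage)` stays below 7 px at any
tested coverage — inside the reach of both the RVDA opening (radius 3)
and the FAZ opening (radius 5), exactly as capillary spacing is in a real
deep-plexus scan. Strokes are erased inside a central avascular ellipse
(the FAZ) and optional rectangular patches; per-zone coverage is then
adjusted pixel-wise to hit its target exactly over the perfused support
(zone 1 is mostly the avascular zone itself, so targets are defined
outside it), and the reported per-zone truth is the exact stroke-mask
fraction over the full zone. Intensities: background 10 ± 6, vessels
180 ± 20, global noise sd 5. The broad vessel spread diffuses the
vessel-edge contribution to the range histogram so the background peak is
always the dominant mode, and both intensity tails stay clear of the
0/255 clip (a clipped co-occurrence of 0 and 255 in one window would
spike bin 255). The background spread is the texture knob: widening it
broadens the range histogram, moving FC and FWHM up monotonically without
touching any segmentation threshold.

*B-scan phantoms* place two bright bands (inner surface, deeper layer) on
a dark background and displace the upper band downward with a smooth
Gaussian pit; truth thickness is the band separation at the pit column.

*Cohorts* default to the study shape (99 normal / 22 MCI / 28 AD) with
full-effect disease meaning −15 percentage points coverage, FAZ semi-axes
× 1.5, +6 texture sd and −5 px band separation; MCI receives half the AD
effect. These magnitudes are phantom parameters chosen to be large and
unambiguous, not claims about pathology. Every subject derives its own
RNG stream from the master seed, so cohorts are reproducible and
order-independent; the same spec and seed give byte-identical images and
feature CSVs.

What the phantoms do **not** emulate — and hence what passing tests do
not establish about clinical data: OCT speckle statistics, real capillary
morphology and branching, segmentation artefacts of the device pipeline,
media opacity, motion residue, and any overlap structure between classes
(effects are injected, so separability on phantoms says nothing about
clinical effect sizes). Recovery accuracies measured on phantoms
(FAZ area, per-zone density, thickness) are statements about the
extractors' numerical correctness, not about clinical validity.

## Problem sizes and numerical tolerances in the test suite

The suite exercises full-size 600 × 600 phantoms where spatial scale
matters: 20 phantoms across FAZ radii 30–80 px for FAZ recovery (area
within ±10 %, centroid within 2 px), 20 phantoms with per-zone coverages
20–60 % for density recovery (±5 percentage points), and 20 B-scans with
separations 8–25 px and noise sd up to 10 for thickness (±1 px; the
acceptance B-scans use 5-px bands so the profile valley at the 8-px
separation bound spans at least three rows, the minimum the width-3
smoothing can resolve). The end-to-end check simulates the 99 + 28
normal/AD cohort and requires the FWHM–VD Gaussian-kernel model to reach
90 % resubstitution accuracy and 0.9 AUC under the default effect sizes.
Structural tests run on smaller phantoms (220–360 px) where only topology
matters. Moment identities are exact; centroid equivalence is asserted at
1e-9; FWHM of discretised Gaussians is asserted within 2 bins of
`2 sqrt(2 ln 2) sigma`.

## Known limitations

* The five-zone geometry is one reading of an under-specified grid; true
  ETDRS sectors (nine, with fixed millimetre radii) are intentionally not
  implemented.
* Sensitivity as `TP/(TP+FP)` is kept for comparability with the original
  report even though it is a precision; always read it together with
  `sensitivity_canonical`.
* Resubstitution metrics on 1–2-feature SVMs are optimistic; the
  cross-validated companion numbers are the ones to trust for
  generalisation.
* The thickness measurement is single-column by design; it inherits the
  pit-localisation error and does not average across the fovea.
* `pixel_scale_mm` conventions differ between device reports and scan
  field sizes; the default (0.05 mm/px) follows the report convention for
  these scans but should be set explicitly for other hardware.
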
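---
title: "Measuring pericardial effusion width from echocardiography clips"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pericardial effusion width from echocardiography clips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pewidth)
```

## The problem

Pericardial effusion (PE) — fluid accumulating in the pericardial sac — is
diagnosed and graded on transthoracic echocardiography, where it appears as
an echo-free rim around the heart. The clinically decisive number is the
maximal width of that rim: below 1 cm the effusion is small, between 1 and
2 cm moderate, above 2 cm large. Manual measurement is operator-dependent;
`pewidth` implements an automated pipeline that goes from a raw multi-frame
ultrasound clip to a calibrated width and a severity grade:

1. **Moving-window view selection (MWVS).** A per-frame view classifier
   scores every frame over the five view classes (PLAX, PSAX, A4C, SC,
   OTHER); a 48-frame sliding window selects the best run of consecutive
   qualifying frames, or rejects the clip.
2. **Segmentation.** A pluggable per-frame segmenter produces a binary PE
   mask (and optionally chamber masks) for each selected frame.
3. **Maximal width calculation.** A geometric procedure measures, per
   frame, the longest boundary-normal chord through the PE mask, takes the
   per-clip maximum, and calibrates it to centimetres with the clip's
   pixel spacing.
4. **Grading and evaluation.** The width is graded by the clinical bins,
   and the package ships the agreement/classification metrics used to
   score such pipelines (Dice, MAE, ICC, R², ROC AUC with DeLong CI,
   sensitivity/specificity).

The trained networks that produce view scores and masks in a clinical
deployment are deliberately *pluggable*: any function returning five
probabilities per frame is a classifier, any function returning a
`segmentation_result` per frame is a segmenter. The package provides
fixtures (a constant classifier, a score-table replayer, an intensity-band
reference segmenter) so the full pipeline runs and can be validated
without any trained weights or clinical data.

## Moving-window view selection

Frame quality is judged per frame: the top-scoring class must be one of
the four primary views with probability at least `frame_quality_floor`
(default 0.5). A window of `window_length` frames (default 48, stride 1)
is a candidate only if *every* frame qualifies; the alternative reading —
that half the window's frames suffice — is rejected because the quality
criterion is applied to individual frames, but both floors are exposed in
`selection_config()`. Candidates are ranked by majority-vote count of
their frames' top classes, then mean top-1 probability, with exact ties
(beyond float jitter, compared at 1e-12) resolved to the earliest start.
The winning window must finally clear `mean_confidence_gate` (default
0.8) on its mean top-1 probability. Clips shorter than the window are
rejected, not padded.

```{r mwvs}
stream <- make_score_stream(100, start = 41, length = 55, view = "A4C",
                            confidence = 0.95)
select_window(stream)
```

## The maximal width calculator

For each frame the calculator iterates over image rows (the vertical
axis), drawing a hypothetical horizontal line per row. Each intersection
of that line with the mask — every background/foreground transition along
the row — anchors a chord:

* the inward **boundary normal** at the crossing pixel is taken from the
  gradient of the Gaussian-smoothed mask indicator (sigma 2 px). This
  field is the numerically stable choice: finite differences of the raw
  mask or of its distance transform at a staircase boundary pixel can be
  tens of degrees off, and the distance-transform gradient additionally
  rotates to point *along* a protrusion near medial-axis shoulders.
  An ordered-contour tangent estimator (`boundary_normal()`, principal
  direction over a ±3-point window with the gradient field as fallback)
  is exported and tested, but the frame-level measurement uses the
  gradient field uniformly, so that the per-point chord value does not
  depend on whether a pixel happens to sit on a traced contour;
* the **chord** is measured by marching from the crossing along the
  normal in `ray_step` steps (default 0.05 px), sampling the mask by
  nearest neighbour; out-of-grid counts as background and interior holes
  terminate the chord. The exit is refined to the midpoint between the
  last inside and first outside samples. A ray that never leaves its
  starting pixel measures zero;
* **exit-side consistency**: a chord that lands obliquely on the far
  boundary is an inflated secant — the signature of a misoriented entry
  normal near a corner. The chord is re-measured from its landing pixel
  along *that* boundary's normal, and the shorter of the two is kept.
  Genuine axial chords (e.g. down the long axis of a lobe) land
  perpendicular and are unaffected; oblique corner secants on a
  rectangle collapse to the true side width;
* **degenerate collinear runs**: a foreground run of at least
  `collinear_run_px` (default 12) pixels lying flat along a horizontal
  stretch of boundary meets the scanline edge-on; such runs yield no
  crossings, because their vertical extent is measured by crossings on
  the perpendicular edges. Shorter flat runs — the rounded tips of
  lobes — keep their crossings so axial chords are not lost.

The frame's width is the maximum over all crossings (ties to the smallest
row, then leftmost column); the clip's width is the maximum over frames
(ties to the earliest frame); empty frames contribute zero. Components
smaller than `min_region_area` (default 10 px) are ignored so
segmentation specks cannot drive the reported width. Calibration uses the
chord's endpoint displacement under the (possibly anisotropic) pixel
spacing: `sqrt((drow * spacing_row)^2 + (dcol * spacing_col)^2)`.

These defaults were set against analytic phantoms at 100-px scale: a
disc's maximal normal chord is its diameter, a full annulus's its rim
thickness, an axis-aligned rectangle's its horizontal width. All are
recovered within a fraction of a pixel:

```{r phantoms}
frame_max_width(make_phantom("disc", grid = c(256, 256), radius = 100)$mask)
frame_max_width(make_phantom("annulus", grid = c(300, 300),
                             outer_radius = 120, inner_radius = 90)$mask)
```

Irregular shapes have no closed form, so the suite cross-checks
`frame_max_width()` against a brute-force reference that sweeps every
crossing of every row with independently recomputed normals and 0.02-px
marching; on 50 seeded random blobs the two agree to well under 1%.
Two caveats define what this check can and cannot show. First, the width
of a pixelated region along an estimated normal is genuinely ill-posed at
sharp corners, and near-grazing chords change length discontinuously with
direction — which is why the measurand itself includes the exit-side and
collinear-run rules above, and why the reference shares those definitions
while re-deriving everything else. Second, a literal sweep of *all*
boundary pixels would measure tall shapes through their flat tops (a
40 × 200 rectangle would score 200, not 40); the scanline method is
deliberately anchored at horizontal-line intersections, matching how the
width of an effusion rim is read on a vertical image axis.

## Severity grading

`grade_effusion()` is a monotone step function with the boundary
convention SMALL = (0, 1) cm, MODERATE = [1, 2] cm, LARGE = (2, Inf) cm —
the "1–2 cm" bin read as inclusive, consistent with its strict "< 1" and
"> 2" neighbours. `presence_floor` (default 0) exists because segmentation
noise can produce tiny positive widths; any width at or below it grades
NONE. For ROC analyses the continuous width itself is the detection score
(`presence_score()`): AUC depends only on score order, so no threshold
needs to be fixed to evaluate detection of "any effusion" or "moderate or
worse".

## Evaluation metrics

`icc()` is the two-way random-effects, absolute-agreement, single-measure
ICC — ICC(2,1), the standard form for method-vs-expert agreement — with
the 95% CI from the F-distribution method; it was verified against an
independent statistics package to 1e-6. Absolute agreement penalises
systematic offsets, so a perfectly correlated but shifted rater scores
below 1 while R² stays at 1 — the suite asserts this distinction.
`roc_auc()` uses midrank tie handling and a DeLong CI (seeded stratified
bootstrap as the alternative). Dice on two empty masks is defined as 1
(perfect agreement about absence); empty versus non-empty is 0.

## Synthetic data: what it emulates, and what it does not

The generators produce every fixture the pipeline needs, each with known
ground truth:

* `make_phantom()` — disc, annulus, rectangle (analytic widths), crescent
  and random smoothed-noise blobs (reference-checked only; a crescent's
  maximal chord can jump to the outer diameter, so no closed form is
  claimed). Blob draws whose largest component touches an 8-px border
  margin are rejected and redrawn, since every phantom must fit the field
  of view.
* `make_effusion_video()` — a "beating" clip whose full-annulus rim
  thickness follows `t(f) = t0 + a sin(2π (f − 1) / period)` (defaults
  t0 = 20 px, a = 10 px, period 24 frames, 48 frames), so the clip
  maximum `t0 + a` occurs a quarter period in, emulating measurement of
  the thickest point across a cardiac cycle. The full-annulus geometry is
  chosen because its normal chords equal the rim thickness analytically.
  With `render = TRUE` frames become 0–255 grayscale with a dark
  background, mid-intensity inner disc and bright fluid band under
  multiplicative uniform speckle (±15%), deterministic in `noise_seed` —
  separable by the reference band segmenter, which is all the rendering
  needs to support.
* `make_score_stream()` — classifier-output streams with a planted
  qualifying window.
* `write_synthetic_dicom()` — uncompressed explicit-VR little-endian
  multi-frame DICOM with calibration as PixelSpacing (mm/px), as an
  ultrasound-region sequence (cm/px), or absent.

None of this is ultrasound physics: there is no attenuation, shadowing or
sector geometry, effusions are symmetric rims rather than loculated
collections, and the fixture classifiers are noiseless. Passing tests
therefore demonstrate that the *measurement machinery* — selection logic,
geometry, calibration, grading, metrics, file formats — is correct, not
that any particular trained model segments clinical images well; the
trained components are exactly what the pluggable interfaces leave open.

## Input/output conventions

DICOM reading supports uncompressed little-endian transfer syntaxes
(explicit and implicit VR), 8/16-bit grayscale and interleaved RGB (luma
conversion), MONOCHROME1 inversion, and calibration priority
PixelSpacing (mm → cm) over ultrasound-region physical deltas (cm); a
file with neither yields an explicit calibration-missing error, never a
silent default. Mask annotations travel as one 0/255 PNG per structure
with a JSON sidecar, or as a run-length CSV dialect
(`structure,row,col_start,col_end`); both round-trip bit-exactly. Clip
reports are written as a one-row-per-clip CSV summary and a full-detail
JSON that reproduces the reports on reading. All indices are 1-based in
the R API; external score tables keep their own frame labels, and
reported windows use those labels.

## Problem sizes and determinism

The test suite and the acceptance script use 96–320 px grids, 48-frame
clips and simulations of n = 200, sizes at which every analytic check is
meaningful while the whole suite runs in minutes on one core. All
randomness (speckle, blobs, simulation draws) flows through explicit
seeds; identical seeds give bit-identical fixtures and reports.

## Known limitations

* The width of a region along a boundary normal is ill-defined at exact
  corners; the measurand's exit-consistency rule resolves this in favour
  of the local width, which is the clinically sensible reading.
* Regions thinner than ~2 px or flatter than one scanline measure zero
  (their runs never leave the starting pixel, or are edge-on); the
  minimum-area filter makes this irrelevant at realistic rim widths.
* One window is selected per clip; overlapping qualifying windows from
  different views in a single clip are not split into multiple outputs.
* The per-clip width is the maximum over all selected frames; an
  end-diastolic-frame restriction would require ECG gating information
  the pipeline does not consume.
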
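---
title: "Measuring wound area from grid-calibrated boundary tracings"
author: "planimetr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring wound area from grid-calibrated boundary tracings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planimetr)
```

## The measurement model

The input is a scanned raster image of a closed wound boundary drawn with a
pen on a transparent ruler printed with a centimetric grid (1.0 cm cells;
the default sheet is 22.0 cm × 17.0 cm, a 374 cm² measurement area). Three
facts about this input drive the design:

* the grid is a *calibration object*: its line spacing is exactly one cell,
  so the pixel scale per axis can be estimated from the image itself rather
  than declared by the user;
* the grid is also *noise*: its strokes must be removed before the traced
  region can be isolated, without cutting the trace where the pen crosses
  (or runs along) a grid line;
* the pen stroke has finite width and straddles the anatomical boundary the
  clinician followed, so "the traced region" is ambiguous by up to one
  stroke width unless a convention is fixed.

The pipeline (`segment_trace()`) is: binarize → calibrate → remove grid →
close pen gaps → flood-fill the exterior. Measurement then integrates the
interior pixels (area), measures the boundary polyline (perimeter), and
applies rotating-calipers geometry for the clinical axes C and L.

## Binarization and calibration

Binarization defaults to Otsu's threshold on the 256-bin intensity
histogram (`binarize()`), with a fixed threshold as an override; ink is
assumed dark-on-light, with a polarity flag. Scans of pen on a transparent
sheet over white backing are strongly bimodal, so the choice of method is
not delicate.

`detect_grid_scale()` first estimates the grid rotation by maximizing the
sharpness (sum of squared bin masses) of the ink-coordinate projection
histograms over candidate angles (coarse 0.25° grid on ±3.5°, then a golden
-section refinement), then reads grid-line positions per axis as
projection-histogram bands: a 1-px bin belongs to a line when it holds more
ink than 40% of the perpendicular image extent — grid strokes span the
whole sheet; the trace never does. The scale per axis is the **median**
inter-line spacing divided by the cell size (median, not mean, so one
missed or spurious line cannot shift the estimate); the two axes are
estimated independently, so anisotropic pixels are supported. Fewer than 4
lines on either axis or a spacing coefficient of variation above 20% are
hard errors rather than silent degradation. On synthetic sheets the scale
is recovered within 0.5% when axis-aligned and within 1% under a 2°
rotation, with the angle itself recovered within 0.1°.

The pipeline de-rotates the binary mask (nearest-neighbour, about the image
centre) whenever the detected angle exceeds 0.2°. This is stricter than a
"report only" convention: the band-based grid removal below needs
row/column alignment to a fraction of a stroke width over the sheet's ~10³
pixels, and a nearest-neighbour rotation of a binary mask is cheap and
deterministic. The angle reported in the calibration is still the scan's
angle, not the post-deskew residual.

## Grid-stroke removal

Grid removal works on the same band model: all pixels inside a detected
line band are *candidate* grid ink. A band pixel is rescued as pen ink only
when off-band ink lies on **both sides** of the band within reach
(band width + 1 px, with ±1 px lateral slack): true where the pen crosses
the line, true where the pen runs tangentially along it (the stroke,
0.03 cm, is wider than the grid line, 0.02 cm, so it sticks out on both
sides), and false on the bare grid line. At band *intersections* the
corner is two bands wide and a ~45° stroke can cross it without satisfying
either the column or the row test, so diagonal opposite-side evidence is
additionally accepted there. The few pixels this still misclassifies
(measured: under 1% of the stroke's pixel count in either direction) sit at
crossings and are re-bridged by the closing step.

An opening with long line structuring elements was considered and rejected:
a straight run of 0.6 cm fits entirely inside a 0.03 cm stroke whenever the
local curvature radius exceeds ~2.4 cm, so low-curvature trace sections
would be deleted along with the grid, and unrestricted morphological
reconstruction cannot repair this because the trace touches the grid
everywhere it crosses.

`close_boundary()` is a morphological closing with a disc of diameter
`max_gap` (default 0.05 cm): it seals pen lifts and the residual nicks at
grid crossings. Closing cannot bridge gaps much larger than the stroke
width is thick — a 1 cm break is (correctly) an open-boundary error
downstream, not something to repair silently.

## Exterior fill and the stroke convention

`fill_exterior()` paints the background from every border pixel with a
4-connected flood fill. The connectivity pairing is deliberate: ink is
effectively 8-connected (diagonal pen steps stay closed) while the fill is
4-connected, so the fill can neither leak through a diagonal stroke joint
nor be blocked by spurious openings. Pixels that are neither exterior nor
ink are interior candidates; components smaller than 0.05 cm² are treated
as specks, exactly one component may remain (several is an
`ambiguous_interior` error that reports the candidate areas; none is
`open_boundary`).

The stroke convention: by default (`measure_to = "centerline"`) the drawn
stroke is split along its medial line — each ink pixel joins the interior
when its distance transform to the interior is no larger than that to the
exterior. The pen line straddles the boundary the clinician traced, and the
generator's ground truth is likewise the stroke centreline, so this
convention is unbiased; measuring to the stroke's inner rim (available as
`measure_to = "inner_rim"`) subtracts a perimeter × half-width band, a
deterministic −P·w/2 bias that already reaches −2.7% for a 4 cm² wound
with a 0.03 cm pen. Centerline splitting keeps the end-to-end area error
within a few tenths of a percent across the tested 4–50 cm² range.

## Perimeter estimators

Two estimators are exposed because they answer different questions.

* `edge_count` is the literal pixel-adjacency rule: every face between an
  interior and a non-interior pixel contributes its physical edge length.
  It is exact for axis-aligned rectangles but counts the Manhattan length
  of smooth boundaries: a digitized disk of radius r converges to 8r, a
  factor 4/π ≈ 1.27 too long. The estimator is kept, clearly labelled, as
  the faithful reading of the classical adjacency definition.
* `contour` (default) measures the marching-squares boundary polyline and
  multiplies by the standard digital chain-length calibration factor
  π(1+√2)/8 ≈ 0.9481. The raw marching-squares polyline, made of axis and
  45° segments, overestimates smooth boundaries by a measured ~5.5% on
  digitized disks (the analytic average of cos θ + (√2−1) sin θ over an
  octant is 1.0548); the calibration factor cancels this to within ±0.1%.
  The factor assumes near-isotropic pixels and smooth outlines — for a
  perfect axis-aligned rectangle `edge_count` is the exact choice.

Because the calibrated contour estimate is unbiased, its fluctuation around
the truth means the isoperimetric ratio P²/(4πA) of a digitized *disk* can
dip a fraction of a percent below 1; the inequality is a meaningful check
only away from the circular equality case.

C and L (`principal_axes()`) are the maximum Feret diameter over the convex
hull of boundary pixel centres and the maximal extent perpendicular to it —
the orientation-free definition of the clinical "greatest length × greatest
perpendicular width", with ties broken toward the smallest angle. Pixel
-centre geometry understates each axis by up to one pixel, negligible at
the default 100 px/cm.

`grid_count_area()` automates the clinician's manual square count: cells
fully inside the interior count as whole squares; partially covered cells
contribute their pixel-measured coverage. By construction the total equals
the pixel area up to the full-cell quantization, and the full/partial split
is reported so the result can be read the way the manual estimate is.

## Healing statistics

`contraction_percentage()` implements the weekly contraction
COi = 100·(S0 − Si)/S0 (positive = shrinkage; negative values occur
transiently after debridement), `build_series()` carries the identity
normalized ≡ 1 − COi/100, and `classify_healing()` applies four literal
predictor rules from the wound-care literature (≥10–15% mean weekly
contraction; ≥25% at week 2; ≥20–40% within weeks 2–4; ≥40% by week 4).
Threshold boundaries are **inclusive**: the sources state ranges without
open/closed qualification, and counting an exact 25% two-week reduction as
"predicted to heal" is the reading consistent with using the lower bound of
a quoted range as the decision point. The weekly rule aggregates
consecutive-week contractions by their mean, since a per-week rate is
quoted without an aggregation rule. The windowed 2–4-week rule returns
`indeterminate` when the threshold is unmet but week 4 has not been read —
the only rule with a genuinely incomplete-information state.

Method comparison (`compare_methods()`, `mean_error()`, `pearson_r()`)
preserves signed errors throughout: clinical comparison tables mix over-
and under-estimates, and a signed mean (where cancellation is informative)
is what such tables print. Absolute-error summaries can be derived but
never replace the signed ones.

## The synthetic generator and what passing tests mean

`make_shape()` produces circles, ellipses, and irregular star-shaped
"blob" outlines r(θ) = r₀(1 + Σₖ aₖ sin(kθ + φₖ)) with seeded harmonics,
amplitudes damped by 1/k and capped at a total of 0.32 so the radius stays
positive and the outline simple. `render_trace()` rasterizes the grid and
the stroke (a constant-width band around the polygon path) at a chosen
resolution, optionally rotated (exactly, in continuous coordinates — no
resampling) and with seeded Gaussian intensity noise; ground truth is the
polygon's shoelace area and chain perimeter. Rendering is binary by
default so that thresholding recovers the exact stroke mask in oracle
tests; an anti-aliasing ramp is available for realism.

Defaults chosen once as the study conditions: 100 px/cm scan resolution and
a 0.03 cm pen stroke (plausible for a flatbed scan of a fine permanent
marker; the clinical workflow does not pin these down), 0.02 cm grid
strokes, no noise (robustness to noise sd = 0.08 is covered by a dedicated
test). The accuracy contract verified by the test suite — area within 2%,
calibrated contour perimeter within 3%, scale within 1% including 2°
rotations, on 20 seeded shapes of 4–50 cm² (measured headroom is roughly a
factor of five inside those bounds) — runs at these conditions on sheets
sized to each shape plus 2 cm margins, which keeps the whole suite around
half a minute.

What the generator does **not** emulate, and the tests therefore do not
certify: paper texture and scanner vignetting, pen-pressure variation and
ink blobs, perspective or lens distortion (flat sheets are assumed
scanned, not photographed), exudate smearing under the transparent sheet,
and genuinely self-intersecting tracings. A real-scan validation would be
needed before clinical use.

## Numerical choices and degenerate inputs

* Stroke rasterization uses pixel-centre point-to-segment distance with a
  small ε tolerance at the exact stroke edge so that integer-resolution
  geometry does not flicker with floating-point rounding.
* Calibration needs ≥4 lines per axis; blank or grid-free images raise
  `no_grid` rather than guessing a scale.
* `binarize()` on a constant image is a `degenerate_histogram` error
  (Otsu is undefined there).
* Empty masks: area/perimeter return 0 with a warning; axes raise
  `no_region` (there is no meaningful direction to report).
* The Kundin coefficient is the literal clinical constant 0.785, not π/4;
  on an exact ellipse the estimate therefore sits 0.05% *below* the true
  area, which is why the "Kundin circumscribes the pixel area" ordering is
  asserted with a small slack on ellipses and strictly on irregular shapes.
* Ties in the Feret diameter are broken by the smallest direction angle,
  making C/L deterministic on symmetric masks.

## Known limitations

* Grid removal relies on the pen stroke being wider than the grid stroke
  (in pixels). Below ~100 px/cm a 0.03 cm pen rasterizes to about the same
  2 px as the grid line, and a stroke running nearly parallel inside a
  grid band can be cut beyond what closing repairs, surfacing as an
  `open_boundary` error. Scans at 100 px/cm (~254 dpi) or finer are the
  supported operating range for segmentation; calibration alone works from
  50 px/cm.
* Grid removal and square counting assume the (deskewed) grid is axis
  -aligned; perspective and barrel distortion are out of scope.
* The contour perimeter calibration targets smooth boundaries; for
  deliberately polygonal regions with long axis-aligned edges, use
  `edge_count`.
* Wounds larger than the sheet, or multiple wounds traced on one sheet,
  are not segmented automatically (the largest-component rule plus the
  ambiguity error make the second case loud, not silent).
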
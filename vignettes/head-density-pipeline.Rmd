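---
title: "From crop-head detections to planting rows and density maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From crop-head detections to planting rows and density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paniclepipe)
```

## The problem

Head (panicle) density — heads per metre of planting row and heads per
square metre of ground — is a major component of grain yield in tillering
crops such as sorghum, and the quantity an agronomist scouts for in the
weeks before harvest.  Deep-learning detectors can now find individual
heads in UAV RGB imagery, but a detector's raw output is just a pile of
per-image bounding boxes.  `paniclepipe` implements everything that has
to happen *after* detection to turn those boxes into agronomically
meaningful numbers:

1. **Preprocessing** — center-crop away lens-distorted edges, rescale
   all images to a common ground sampling distance (GSD).
2. **Planting-row detection** — fit the row lines `y = a x + b` to the
   box centers of each image with an iterative RANSAC.
3. **Quasi-mosaic composition** — place each image's detections into a
   GPS-anchored grid of field cells, removing overlap duplicates by
   construction.
4. **Statistics** — per-row linear densities, per-image areal densities,
   along-row gap records, 1-D row profiles, and a field-wide moving-sum
   density map with sum-one Gaussian smoothing.
5. **Evaluation** — IoU matching, average precision at 0.5 IoU, and
   per-image count MAE/RMSE for whatever detector produced the boxes.

The package is detector-agnostic: boxes arrive as COCO-style JSON or a
flat CSV, with an image-metadata sidecar giving pixel geometry, GSD and
camera GPS.  A synthetic-field simulator stands in for the detector so
every stage is testable against exact ground truth.

## The synthetic field model

`generate_field()` draws a field of parallel planting rows.  Head
positions along each row follow a homogeneous 1-D Poisson process;
perpendicular scatter is Gaussian.  The defaults are the study
conditions throughout the test suite:

* **row spacing 0.75 m** — standard sorghum row spacing;
* **6 heads per row-metre** — a planting density of 80 k plants/ha at
  0.75 m spacing is 6 plants per metre of row, with one head per plant
  at the modelled growth stage;
* **cross-row jitter sd 2 cm** — the visible scatter of head centers
  about the row line;
* **head diameter 10 cm** — sets the simulated bounding-box size.

Unsown spans ("gaps") are carved out of rows after placement, so a
2 m planted gap contains no heads by construction.
`capture_images()` flies a serpentine grid of nadir camera positions
over the field and emits, for every head inside a footprint, one box in
that image's pixel frame; heads in overlap zones appear in every
covering image.  `corrupt_detections()` adds the three error modes of a
real detector — misses, spurious boxes, and center jitter — with
truncated-normal confidences (false positives drawn at a lower mean so
precision–recall curves are non-degenerate).  The detector-noise rates
are free parameters: the published error rates of trained CNNs on real
imagery are not known per-image, so no calibration to a particular
detector is attempted.

What the simulator deliberately does **not** model: canopy appearance,
illumination, occlusion between heads, genotype or growth-stage
differences, camera tilt, and GPS error.  Passing tests therefore show
that the *geometry and statistics* of the pipeline are correct, not that
any particular detector is accurate on real fields.

## Row detection

Row fitting uses the classic RANSAC recipe, run repeatedly: sample
`n = 2` points, fit a line by least squares, collect every point within
a perpendicular distance `t` of the line, and accept the candidate when
more than `d` additional points agree; accepted inliers are removed and
the search repeats until no model reaches `d` or fewer than `n` points
remain.

Two scoring choices matter and were settled empirically:

* **Residual metric.**  Inlier tests use perpendicular point-to-line
  distance, not vertical offset, so the procedure stays honest for
  steep pre-rotation slopes.
* **Model ranking.**  Among accepted candidates the winner is the one
  with the **largest consensus set**, ties broken by the lower mean
  perpendicular residual.  Ranking by mean residual alone looks
  attractive but fragments rows: a slightly tilted line through a
  short, locally tight segment of a row beats the full-row fit on mean
  residual, and a 5-row field comes back as 7 fragments.  Consensus
  size first is the standard cure.
* **Inlier threshold.**  The default is `t = 0.15 x row spacing` in
  pixels (45 px for 75 cm rows at 0.25 cm/px), roughly 3 sigma of the
  cross-row scatter at that scale.  The band must stay well below half
  the row spacing: under consensus ranking, a band of width `t` lets a
  diagonal line with slope `a` collect inliers from each row it crosses
  over an x-range of `2t/a`; once `4t` exceeds the row spacing, a
  diagonal spanning two rows can out-vote a true row.  `t` is exposed
  in every API and in the pipeline configuration.

**Dominant direction.**  Scattered or sparse images can seed RANSAC
badly, so the prevailing row angle is estimated first on the densest
`ceil(W/3) x ceil(H/3)` sub-window (stride `W/10`), then each image is
rotated so rows run horizontal before the full multi-row search.  Fits
are attempted in both axis orders and the larger consensus wins, which
keeps near-vertical rows finite (`|theta| > 45` degrees simply wins in
the swapped frame).  Per-image estimates are aggregated into a field
consensus by a robust cluster mode (the heaviest 10-degree cluster under
the axial metric, weighted by detections per image): field-edge images
that see only a sliver of each row systematically lock onto the
*cross*-row direction, 90 degrees off, and drag any plain or circular
mean (we observed a -15 degree "mean" on a field whose true orientation
was 0).  Images whose own estimate falls outside the winning cluster are
rotated by the consensus instead.

Rows whose fitted angle still deviates from the dominant direction by
more than 10 degrees are discarded and their points pooled for one refit
pass; refit rows are kept only if they agree with the direction.  The
pseudo-code ambiguity of what happens to such rows is thereby resolved
as *discard-then-refit-once*.

## Quasi-mosaic

A photogrammetric orthomosaic is overkill for counting.  Instead the
field is covered by a grid of `m x m` cells anchored at a reference GPS
point; each cell is filled by the single image whose camera is nearest
the cell center *among those whose footprint fully covers the cell*
(ties to the lexicographically smaller image id).  Detections of the
assigned image are rotated by that image's horizontal correction,
converted to metres via the GSD, translated by the camera position, and
kept only inside the half-open cell rectangle.  Because cells partition
the plane, a head seen by five overlapping images is counted exactly
once — duplicate suppression is purely geometric, with no box merging or
non-maximum suppression across images.

The full-coverage requirement has a quantitative consequence worth
stating: the nearest camera can fully cover every cell touching the
field only when the camera spacing is at most `footprint - cell` and the
flight margin is at least `cell / 2`.  With cells at 80% of the
footprint (the generic `default_cell_size()`), that forces more than 80%
overlap; the pipeline configuration therefore defaults to 60% overlap
with cells at 50% of the *cropped* footprint, which meets the same
condition at a practical image count.  Under that geometry, a noiseless
detector and zero cross-row jitter, the composed field detection set
equals the ground-truth head count *exactly* — the conservation property
the test suite asserts.  Camera positions are taken as the principal
point at nadir; no tilt model is attempted, consistent with the "quasi"
accuracy goal.

## Density statistics

For an image of width `W` px and GSD `G` cm/px with `C_r` heads on a
row, the row density is `C_r / (W G)` heads/cm, reported as heads/m; the
image density is `C_i / (W H G^2)` heads/cm^2, reported as heads/m^2.
When a detected row's inlier span does not traverse the image (less than
90% of `W`), the span length is used instead of `W` and the substitution
is flagged in the output (`length_source`).

**Gaps.**  Along-row head positions are scanned for consecutive
intervals (including the span edges) longer than 50 cm.  An empty row
longer than the threshold is reported as one whole-span gap — the
agronomically useful reading.  Note the base rate: for Poisson spacing
at intensity `lambda` the probability that an *ordinary* interval
exceeds 50 cm is `exp(-lambda/2)` — 8.2% per interval at 5 heads/m,
5.0% at 6, 3.0% at 7.  Sparse rows will always produce some spurious
gap records; the gap list is a screening tool, not a proof of a sowing
fault.

**Row profiles and the field map.**  The 1-D profile is a 100 cm moving
sum at 1 cm steps divided by the window length (heads/m), then smoothed
with a sum-one Gaussian (sigma 25 cm).  The field map rasterizes the
field-frame detection centers at 1 cm/px and takes a 100 x 100 px moving
sum with stride 1, so each value is directly heads per square metre;
smoothing uses a sum-one 2-D Gaussian with `sigma = window/6` px.  The
kernel is 101 px on a side rather than 100: an even kernel has no center
pixel and would shift the whole map by half a pixel.  Because the kernel
sums to one, smoothing redistributes but does not create or destroy
density — the interior mean of the smoothed map stays within 0.1% of the
raw moving-sum mean on a homogeneous field.  Windows truncated at the
field boundary are renormalized by their covered fraction; the
`coverage` matrix in the returned object flags those edge positions,
whose values are noisier by construction.  The moving sum itself is
computed exactly (integral image, integer counts); the Gaussian pass is
exact separable convolution, and both are verified against brute-force
double-loop oracles to 1e-9.

The window and sigma values are conventions, not fitted constants; all
are configuration parameters.

## Evaluation metrics

Matching is greedy in descending confidence: each detection takes the
unmatched ground-truth box of highest IoU at or above 0.5 (ties to the
lower ground-truth index); unmatched truths are false negatives.
Average precision integrates the all-point-interpolated precision
envelope (the COCO convention for a single IoU threshold; the choice is
recorded in the output metadata).  Count MAE/RMSE are computed per
image.  These metrics evaluate whatever detector produced the input —
the package ships no detector and makes no claims about any published
model's accuracy.

## Numerical and design notes

* Every stochastic operation takes an explicit integer seed and restores
  the caller's RNG state; identical configurations give bit-identical
  outputs, end to end (asserted by byte-comparing pipeline output files).
* Degenerate RANSAC samples (vertical or coincident points) are
  resampled, never fitted; an image with too few detections yields an
  "insufficient data" condition and inherits the field consensus
  direction.
* Nearest-row ties break toward the lower row index (rows are sorted by
  intercept); cell-membership intervals are half-open so boundary
  detections belong to exactly one cell.
* The local GPS projection is equirectangular about the field reference
  point (`R = 6,371,000` m); for fields under a kilometre the curvature
  error is far below the GSD.
* A "3 collinear points with n = 2, d = 2" corner case cannot form a row
  under the literal consensus rule (only one point remains after
  sampling, and acceptance needs more than `d` additional inliers); the
  single-row property is instead exercised with 8 collinear points at
  `d = 5`.

### Problem sizes used by the test suite

The suite favours many moderate problems over few huge ones: 20 fields
of 5–12 rows for row recovery; 50 seeds per density in 3–6 heads/m^2
for density recovery (interior means taken over an integer number of
row spacings, so the row-stripe ripple of the moving window integrates
out); 100 seeded fields for gap recovery at 7 heads/m, where the
analytic spurious rate `exp(-3.5)` is comfortably below the 5% bound
(at 5 heads/m the base rate alone is 8.2%, so no implementation could
meet the bound there); 200 corruption seeds for the recall plateau; a
300 x 300 px field for the brute-force map oracles.

## Known limitations

* Rows are straight lines; curved or contour-planted rows are out of
  scope, as is detecting rows from raw imagery without a detector.
* The quasi-mosaic trusts camera GPS; positional bias translates
  directly into the map.  No bundle adjustment is attempted.
* Gap detection inherits detector misses: a missed stretch of heads is
  indistinguishable from a sowing gap.
* The simulator's idealizations (above) mean detector-level conclusions
  must come from real labelled imagery, for which the evaluation module
  provides the metrics.
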
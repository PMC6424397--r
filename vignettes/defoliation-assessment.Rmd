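---
title: "Assessing pine processionary moth defoliation at tree level from UAS products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing pine processionary moth defoliation at tree level from UAS products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defoliatr)
```

## The problem

The pine processionary moth (*Thaumetopoea pityocampa*, PPM) strips
conifer needles over fall and winter; an outbreak leaves a mixed
Mediterranean stand as a mosaic of healthy holm oaks, healthy pines, and
pines defoliated to varying degrees. Managers want that mosaic
quantified *per tree*: which stems are pines, what fraction of each
pine's crown has lost its needles, and a three-level field class
(non-defoliated < 15 %, partially defoliated 15–85 %, completely
defoliated > 85 %).

`defoliatr` implements a desk-scale version of a UAS workflow for this
question. The inputs are the standard products of a photogrammetric
survey: a dense 3-D point cloud and co-registered reflectance
orthomosaics (green, red, red-edge, NIR at 0.15 m, plus RGB). The
pipeline derives terrain and canopy models from the cloud, finds and
delineates individual crowns, classifies crown pixels from two
vegetation indices, and aggregates to per-tree defoliation with a full
accuracy assessment. Because no imagery ships with the package, a
synthetic-scene generator produces all three inputs with known ground
truth, so every stage is testable end to end.

## Pipeline and models

### Ground, DTM, CHM

Ground points are classified by progressive TIN densification with the
conventional parameters `step` = 10 m, `bulge` = 0.5 m, `spike` = 1 m,
`offset` = 0.05 m. Seeds are the lowest point per `step × step` cell; a
seed more than `spike` below the least-squares plane of its neighbouring
seeds is discarded as a low outlier. The seed Delaunay TIN is then
densified: a point joins the ground set when its height above the
current surface is at most `offset + bulge · r`, where the roughness
term `r` is the local facet slope (m/m) times the distance to the
nearest TIN vertex, capped at `bulge`. Accepted points are thinned onto
a halving grid (10 → 5 → 2.5 → 2 m floor), the per-cell top of the
accepted band becomes the next round's vertex set, and the rounds run to
a fixpoint (at most 10). Two implementation choices matter in practice
and are deliberate:

* the TIN is evaluated through a 1 m rasterization sampled bilinearly,
  rather than exact point-in-triangle queries — at 3 × 10⁵ points per
  scene this is what keeps the stage tractable, and the 1 m surface
  resolution is well below the vertical tolerances involved;
* the seed set is anchored at the data boundary (lowest point per 10 m
  segment of a 1 m edge strip), and surface cells outside the TIN hull
  are filled by local-plane extension rather than flat extension.
  Without both, points near the scene edge on sloping terrain sit far
  from any vertex, the extrapolated surface diverges from the terrain,
  and an entire edge strip is misclassified — visible as metre-scale DTM
  bias and phantom "trees" along the boundary.

The DTM is the 1 m grid of mean ground elevations (TIN interpolation for
empty cells), heights are normalized by bilinear DTM subtraction with
negative values clamped to zero (a CHM must be non-negative; points
outside the DTM are dropped and counted), and the 0.5 m CHM takes the
per-cell maximum with an iterated 3×3 median fill for empty cells.

### Tree detection and crown delineation

Treetops are local maxima of the 3×3-mean-smoothed CHM within a 3×3
search window, subject to a 2 m minimum height (default chosen to
exclude shrubs and terrain artefacts; the window sizes are the standard
fixed-window choice at 0.5 m resolution). Ties on perfectly flat
plateaus delegate to the row-major first pixel of the connected
equal-valued plateau, which keeps detection deterministic; on real
(noisy) CHMs exact ties essentially never occur. Apexes report the
unsmoothed CHM height.

Crowns are Voronoi cells around the apexes, restricted to pixels whose
CHM value reaches `exclusion_fraction` (default 0.3) of the apex height
within `max_radius_m` (default 6 m, generous for the stand's crown
sizes), reduced to the 4-connected component containing the apex.
Distance ties between apexes resolve to the lowest tree id. Spatial
agreement with reference crowns is scored with the Sørensen coefficient
`SC = 2A/(2A + B + C)`; intersections are computed exactly by
Sutherland–Hodgman clipping whenever one polygon is convex (reference
crowns are discs) and by fine rasterization otherwise.

### Spectral classification and per-tree scores

NDVI = (NIR − R)/(NIR + R) drives both decisions; ExG on chromatic
coordinates (2g − r − b) isolates shadows. The pixel rule, in order of
precedence: shaded if ExG < −0.06 (regardless of NDVI), else defoliated
if NDVI < 0.27, else non-defoliated. Species is decided per crown from
the mean NDVI over all crown pixels — shaded included, since the shading
model is multiplicative and NDVI is a band ratio; a switch allows
excluding them — with holm oak at mean ≥ 0.42. Defoliation per pine is
`100 · n_def / (n_def + n_non_def)`: shaded pixels are excluded from the
crown surface entirely. Crowns delineated on the 0.5 m CHM are mapped to
the 0.15 m spectral grid by cell-centre containment. The 15/85 class
cutpoints are assigned inclusively to the partial class (the field
definition leaves the boundary open; a closed boundary keeps the
classifier total). Trees whose usable surface is empty (all shaded) are
flagged and excluded from confusion matrices with a warning; nodata
NDVI pixels are excluded from all counts.

The thresholds are exposed as data rather than constants.
`scan_threshold()` reproduces the sensitivity analysis that selects
them: accuracy against reference labels on a 0.01 grid, ties resolved
to the lowest candidate for determinism. On the generator's pixel
spectra the scan recovers the Bayes boundary between the defoliated and
healthy-pine NDVI distributions to within ±0.05.
`unsupervised_shade_threshold()` documents the clustering route to the
shade default: 2-cluster 1-D k-means on crown ExG, threshold at the
midpoint of the centres. One caveat worth knowing: in a heavy-outbreak
scene most crown pixels are brown (ExG ≈ 0.1), so a two-cluster split
separates lit from dark rather than shaded from unshaded and lands well
above −0.06; the operational default corresponds to imagery where the
shade mode dominates the dark tail, and the pipeline always uses the
explicit threshold.

### Validation

Confusion matrices are reference-in-rows; overall accuracy is the trace
fraction, per-class producer's/user's accuracies are row/column-wise,
and agreement beyond chance is standard Cohen's kappa,
`(p_o − p_e)/(1 − p_e)` with `p_e` from the marginals. `merge_classes()`
pools classes (e.g. the two defoliated classes) and drops those excluded
by the grouping (e.g. oaks), conserving the retained counts. The
calibration between estimated and reference percent defoliation is
ordinary least squares with `R² = 1 − SS_res/SS_tot`; a zero-variance
response degenerates to slope 0, R² = 0 with a warning rather than an
error. Printed percentages round half away from zero, matching how
accuracy tables are conventionally printed.

## The synthetic stand

The generator's defaults are the study conditions the package is tested
under: 110 trees — 25 holm oaks and 85 Scots pines split 13/29/43
across the non-defoliated/partial/complete field classes — on a
160 × 160 m scene (packing 110 trees at the 8 m minimum spacing with
headroom; a larger extent would only add runtime), multispectral GSD
0.15 m, CHM 0.5 m, 12 points/m² ground density with canopy surfaces
sampled at twice that, ground vertical noise 0.05 m (canopy 0.03 m),
sun from the south at 45° elevation.

Terrain is a gentle surface: a linear trend plus three sinusoids with
*absolute* wavelengths of 60–180 m (hill scale — proportional-to-extent
wavelengths would make small scenes implausibly steep), rescaled so
total relief stays within twice the configured amplitude (default 3 m).

Trees are hard-core dart throws: pine heights uniform on 5–15 m with
crown radius 0.25 × height, oaks 3–8 m at 0.45 × height; crowns are
exact discs (so truth polygons are exact for overlap scoring) with
conical pine envelopes tapering to 0.2 × apex height at the edge and
hemispherical oak caps. The rendered point cloud covers only 90 % of
each crown radius (`canopy_edge_loss = 0.1`), emulating the way
structure-from-motion surfaces under-reconstruct thin crown edges; the
orthomosaic shows the full crown. This asymmetry is what real data
exhibit, and it keeps CHM-delineated crowns from overhanging onto soil —
without it, mixed edge pixels (soil reads as "defoliated", exactly as in
the operational method, where that class is defoliated-or-background)
bias small healthy crowns upward by ~15 points.

Per-pixel NDVI is drawn from class-conditional normals chosen to
straddle the operational thresholds with overlap — soil N(0.10, 0.03),
defoliated pine N(0.12, 0.05), healthy pine N(0.35, 0.04), oak
N(0.50, 0.04) — and converted to NIR/red pairs of fixed brightness;
these are calibration choices, not estimates of any real site's
reflectance. Within a pine crown exactly `round(f · n)` pixels are
defoliated (`f` the true fraction), placed as a contiguous angular
sector from a random start: clumped like real damage, exact in count
(the mixture calibration holds to 1/n), and radially balanced so a
concentric sub-crown still sees fraction ≈ f. Shadows are cast
height-aware: a pixel is shaded when the sun ray leaving its own surface
height intersects another crown's volume, so soil behind trees is
shaded at full length while neighbouring canopy is only shaded by taller
trees — shadow pixels dim all MS bands multiplicatively (NDVI-preserving)
and recolour RGB so ExG < −0.06 holds for ≥ 99 % of them. All
randomness flows from one scene seed consumed in a fixed order
(terrain, placement, cloud, rasters), so identical configurations yield
byte-identical outputs.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: crown asymmetry and inter-tree occlusion,
under-canopy ground occlusion (ground points exist everywhere),
radiometric calibration error and BRDF, co-registration error between
the RGB and multispectral mosaics — real surveys fly the two cameras at
different times, so their shadows need not coincide; a
`shadow_rgb_offset_m` knob (default 0) exists to study that — and
within-crown self-shading (switchable). Recovery metrics on this
generator are upper bounds on field performance.

## Problem sizes and budgets

The test suite exercises the full 110-tree scene once (~350 k points,
1.1 M spectral pixels; about 2–3 minutes) and uses a 60 × 60 m, 9-tree
scene for per-module checks; the acceptance script regenerates the
110-tree stand from its seed and reruns the pipeline from scratch. These
sizes were chosen so a complete check runs comfortably on a single CPU
while the 110-tree structure of the validation design is preserved.

## Known limitations

* The ground filter's `bulge`/`spike`/`offset` semantics follow the
  documented contract above, not any proprietary implementation; on
  terrain steeper than the seed grid can follow (slopes approaching
  1 m/m at 10 m scale) densification can stall below domes.
* Crown polygons are traced pixel outlines; sub-pixel crown boundaries
  are not represented, which puts a resolution floor (~0.5 m) on
  Sørensen scores.
* The LAS reader/writer covers LAS 1.2 point formats 0/1 (coordinates
  and classification), not the full specification.
* TIFF rasters are written with an affine value scaling recorded in a
  JSON sidecar (TIFF float samples must lie in [0, 1]); the ASCII grid
  format is the primary, fully self-describing text format.
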
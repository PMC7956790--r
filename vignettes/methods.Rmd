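---
title: "Crown and shadow based canopy biovolume: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crown and shadow based canopy biovolume: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olivecanopy)
```

## The problem

Olive orchards are monitored from nadir UAV imagery to track per-tree canopy
size, a proxy for growth and expected yield. Two polygons per tree carry the
signal: the crown outline and the cast shadow. From the crown polygon one
obtains a perimeter; from the shadow and the sun's altitude, a height; the
two combine into an approximate canopy volume ("biovolume"). `olivecanopy`
implements that full chain — plus a synthetic orchard generator with exact
per-tree ground truth, so every stage can be tested end to end without any
field or flight data, and an ingestion contract so the polygons can come
from any external instance-segmentation model instead of the built-in
deterministic segmenter.

## The biovolume model

The canopy is idealized as a cylinder:

* the base is the circle whose circumference equals the crown-polygon
  perimeter \(P\): surface \(S = P^2 / (4\pi)\);
* the height comes from the flagpole relation on flat terrain,
  \(h = L \tan\theta\), where \(L\) is the shadow length along the
  anti-solar azimuth and \(\theta\) the solar altitude;
* the lowest 0.5 m of trunk carries no branches, so
  \(V = S \cdot \max(h - 0.5\,\mathrm{m}, 0)\).

The trunk offset is a `biovolume_config()` parameter (metres, default 0.5).
Heights at or below the offset clamp \(V\) to zero with a warning instead of
erroring: segmentation noise can shorten shadows, and a zero volume is the
honest downstream value.

Estimated volumes are scored against ground truth with
\(\mathrm{accuracy} = (1 - \overline{|V_G - V_M|/V_G}) \times 100\,\%\),
the mean absolute relative error subtracted from one. The mean form is used
deliberately: the reported accuracies of the study this package reproduces
are only consistent with averaging over the \(N = 6\) test trees.

Two solar-altitude constants are shipped (`theta_for_subset()`): 29.61° for
the RGB subsets and 26.22° for the vegetation-index subsets. These are the
only assignments consistent with every reported shadow-length/height pair,
and the package's own NOAA-style `solar_position()` reproduces them from
the site coordinates and the two survey timestamps (evening June flight
→ ~29.59°, winter morning flight → ~26.18°, both within 0.1° of the
constants). The computed position is available as an `override`, so the
constants are defaults, not hard-coding.

## Solar position

`solar_position()` follows the NOAA calculator formulation: Julian century
→ solar declination and equation of time (Meeus-style series) → true solar
time via the longitude correction → hour angle → altitude and azimuth by
spherical trigonometry. Atmospheric refraction is not applied; above 25°
altitude it is below 0.05°, irrelevant at the precision used here.
Timestamps must carry an explicit UTC offset — the function refuses to
assume a civil zone, which is the classic silent error in shadow work.

## The synthetic orchard generator

The generator emulates the study conditions rather than arbitrary scenes:

| parameter | default | rationale |
|---|---|---|
| tree spacing | 6 m grid, jitter sd 0.25 m (truncated at 2 sd) | orchard planting pattern |
| crown radius | uniform 1.0–1.6 m | crown perimeters ≈ 6.3–10 m |
| total height | uniform 2.0–3.5 m | mature olive stature |
| pixel size | 0.03 m (degraded to 0.13 m per subset) | the two survey resolutions |
| sun | altitude 29.61°, azimuth 135° | the RGB-flight altitude; a diagonal azimuth keeps shadows clear of the next grid row |
| trees per patch | 1–8, standard set fixed to 600 total over 150 patches | the dataset shape of the study design |
| reflectance | canopy NIR 0.60 / red 0.12 / green 0.20; soil 0.30 / 0.25 / 0.22; shadow = 0.35 × soil; noise sd 0.02 | NDVI ≈ 0.67 canopy vs ≈ 0.09 soil, separable by threshold |

Crowns are discs (optionally perturbed by a low-amplitude radial harmonic,
which keeps the true perimeter computable by quadrature). Shadows are
stadium-shaped — the dilation by the crown radius of the segment from the
trunk base to \(L - r\) along the anti-solar azimuth — so the cast shadow
has width equal to the crown diameter and tip at exactly
\(L = H/\tan\theta\) from the trunk. Crowns are painted last: nadir imagery
shows canopy, not the shadow beneath it. Because the stadium is tangent to
the crown disc at the trunk, the visible shadow's near-most points sit at
the tangency, and the shadow-length estimator recovers the trunk-to-tip
length rather than an edge-to-tip length.

The spacing invariant (`spacing > 2 × max crown radius`) makes crown overlap
impossible by construction, which is why the reference segmenter needs no
watershed splitting; it only warns when a component exceeds twice the
expected maximum crown area.

Per-patch tree counts are drawn uniformly from 1–8. Because the study's
standard set carries exactly 600 trees in 150 patches (4 per patch on
average, whereas uniform 1–8 averages 4.5), `generate_patch_set()` accepts
an exact `total_trees` and repairs the drawn counts by ±1 steps within the
range until the total matches; `default_patch_set()` applies 600. All
randomness descends from one master seed with per-patch derived seeds
(`seed + patch index`), so patch sets are reproducible while scenes remain
independent.

What the generator does *not* emulate: radiative transfer, terrain slope,
overlapping or touching canopies, weeds and understory clutter, and
within-crown texture. Passing tests on these scenes therefore demonstrate
the correctness of the geometry, the index arithmetic, the evaluation
protocol and the measurement chain — not that a threshold segmenter would
survive real orchard imagery (it would not; that is what trained models are
for, and the ingestion adapters exist so their outputs drop straight in).

## Rasters, indices and resolution degradation

`NDVI = (NIR − Red)/(NIR + Red)` and `GNDVI = (NIR − Green)/(NIR + Green)`
are computed per pixel; zero-denominator pixels are defined as 0 and
counted in a message. Degradation from 3 to 13 cm/pixel uses exact
overlap-area weighting in each dimension (the 13/3 ratio is non-integer, so
block means would be wrong); when the target grid tiles the source the
global mean is conserved exactly, and partial boundary pixels average only
the covered source area. Coordinates follow the raster convention
throughout: 0-based pixels, origin top-left, y down, world north = −y,
polygon vertices at pixel corners in (x = col, y = row) order — the same
convention the VIA annotation format uses.

## Reference segmentation

The deterministic reference segmenter thresholds the crown index (Otsu by
default, parameter-free on the bimodal synthetic scenes; fixed thresholds
are available for regression tests), labels 8-connected components (so thin
diagonal canopy fringes are not split), filters by minimum area, traces
each component's outer boundary along pixel edges and simplifies it by
Douglas-Peucker (default 1 px), which also counters the staircase inflation
of rasterized perimeters (a traced disc boundary is ~27% too long before
simplification, ~2% after). Shadows are segmented the same way on inverted
visible brightness after excluding crown pixels, so canopy is never
mistaken for shadow. An Otsu guard refuses to declare foreground when the
two class means are closer than `min_contrast` (default 0.1): plain Otsu
always finds a threshold, and without the guard a treeless noisy scene
would be split into spurious components.

Confidence is the component's mean index normalized between the threshold
and the scene maximum (clamped to [0, 1]), so a component at the index
maximum has confidence 1 — enough structure for confidence-ordered
matching downstream.

## Evaluation protocol

Matching is the standard detection-benchmark convention: predictions in
descending confidence (ties: larger best IoU, then input order), each
greedily taking its highest-IoU unmatched ground truth; a pair with IoU
strictly above 0.5 is a true positive, any other prediction a false
positive, unmatched truths false negatives. IoU at exactly the threshold
counts as a false positive (the reported rule is strict inequality for
true positives and leaves equality undefined). Bounding-box IoU is the
default — the study's definition names bounding boxes — and mask IoU is
selectable because segmentation models emit masks; the two are never mixed
in one report. The test suite checks the greedy tally against a brute-force
optimal assignment on exhaustive small cases.

Precision, recall and F1 use the standard forms TP/(TP+FP), TP/(TP+FN) and
the harmonic mean, with 0/0 defined as 0. When recomputing the study's
printed tables, agreement is asserted to one unit in the fourth decimal:
the printed values are truncated rather than rounded, and two printed F1
cells differ from the exact harmonic mean by exactly one ulp at that
precision under every rounding convention.

## Numerical choices and degenerate inputs

* Polygon rings are canonicalized to positive shoelace area (y-down frame);
  zero-area and self-intersecting rings are rejected at VIA read with a
  warning, never fatally.
* `mask_to_polygon()` requires exactly one component and returns the outer
  ring (holes are ignored; the painted scenes produce none).
* Boundary tracing resolves 8-connected pinch corners by preferring the
  left turn, keeping diagonally-touching pixels on a single ring.
* Volumes in reported tables are formatted at 1 decimal for P/L/h and 2 for
  V, but always computed from unrounded intermediates — the order that the
  reproduced reference rows require.
* Rasterized shadow lengths are biased slightly short: the visible sliver
  between the crown disc and the stadium side thins below one pixel within
  about \(\sqrt{2r}\) pixels of the tangency, so its extreme vertex is lost
  to rasterization (~5–8 px at 3 cm). On exact truth polygons the estimator
  is within 2 px. The resulting height bias is a few percent, well inside
  the end-to-end volume tolerance.
* One reported volume cell (the RGB-13 estimate for test tree 4) cannot be
  reproduced within 0.1 m³ from its printed inputs — the printed volume
  implies an unrounded shadow length of ~5.07 m against the printed 5.1 m.
  The corresponding acceptance expectation documents this instead of
  widening the tolerance; the other 29 cells reproduce within 0.1 m³.
* The reported RGB-3 overall accuracy (94.51%) is likewise not recoverable
  from the rounded per-tree columns (they give ~94.79%) and is flagged
  `exact = FALSE` in `reference_accuracies()`.

## Problem sizes

The package's own validation uses desk-scale runs chosen once: the standard
150-patch set for counting and splitting checks (truth-only fast path),
eight noise-free patches of 2–5 trees (~30 trees) for end-to-end parameter
recovery, and 5-patch pipeline runs for schema and determinism checks. A
full 150-patch, four-subset `run_pipeline()` completes in well under a
minute on one CPU.

## Design choices that were genuinely open

* **Patch extraction geometry** is not specified by the study design;
  patches here are independent scenes sized to their own geometry rather
  than windows cut from one large orthomosaic. `extract_patch()` exists for
  the windowing case.
* **The segmenter on RGB subsets**: a threshold segmenter cannot find
  crowns in RGB alone, so synthetic subsets keep all bands and differ by
  resolution; the RGB/NDVI/GNDVI labels follow the study's table layout and
  θ constants. Real RGB-only predictions enter through the VIA/mask
  adapters.
* **In the synthetic pipeline all subsets share the scene's sun geometry**
  (one simulated flight); the two per-subset θ constants matter only when
  reproducing the study's reported tables, where the flights differed.
* **Greedy matching over Hungarian assignment**: the benchmark convention,
  and no procedure is prescribed by the source; the brute-force comparison
  in the tests quantifies that the choice is immaterial at orchard
  densities.

## Known limitations

Flat-terrain assumption in the height model; no occlusion handling between
neighbouring shadows (the generator's default geometry avoids it, real
orchards at low sun might not); the perimeter-circle surface overestimates
the area of non-convex crowns by construction; the accuracy statistic is
undefined for zero ground-truth volumes and unstable for very small ones.
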
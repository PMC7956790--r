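# olivecanopy

Per-tree canopy biovolume for olive orchards from nadir multispectral
imagery — and a fully synthetic test bed for the whole measurement chain.

Precision-agriculture workflows estimate tree size from two polygons per
tree in UAV imagery: the crown outline and the cast shadow. `olivecanopy`
implements the geometry that turns those polygons into volumes, the
evaluation protocol for the instance segmentation that produces them, and a
synthetic orchard generator with exact ground truth so the pipeline can be
validated end to end without any flight data. It is aimed at remote-sensing
and agronomy researchers who want the measurement and evaluation machinery
separated from (and testable independently of) whatever segmentation model
produces the polygons.

## The model

For each tree with crown perimeter *P* (m), shadow length *L* (m) along the
anti-solar azimuth, and solar altitude *θ*:

* crown surface (cylinder base): `S = P² / (4π)` — the circle of equal
  circumference;
* tree height (flagpole relation): `h = L · tan(θ)`;
* biovolume: `V = S · max(h − 0.5 m, 0)`, the 0.5 m being unbranched trunk;
* accuracy of estimated vs ground-truth volumes:
  `(1 − mean(|V_G − V_M| / V_G)) × 100 %`.

Detection quality of the crown/shadow instances is scored by greedy
one-to-one IoU matching (bounding-box IoU, TP iff IoU > 0.5) and
precision / recall / F1. Solar altitude and azimuth come from a NOAA-style
solar position algorithm (`solar_position()`), or from the per-subset
constants the reproduced study used (`theta_for_subset()`).

## Worked example

```r
library(olivecanopy)

# a noise-free synthetic patch with 4 trees at 3 cm/pixel
p <- orchard_params(n_trees = 4, seed = 7)
p$reflectance$noise_sd <- 0
scene <- generate_scene(p)

crowns  <- segment_crowns(scene$raster)    # threshold NDVI -> polygons
shadows <- segment_shadows(scene$raster)   # dark, non-crown components
m <- measure_trees(crowns, shadows,
                   theta_deg = p$sun_altitude_deg,
                   azimuth_deg = p$sun_azimuth_deg,
                   pixel_size_m = p$pixel_size_m)
m[order(m$V), c("P", "L", "h", "V")]
#>           P        L        h         V
#> 1  6.401217 4.285067 2.435246  6.310321
#> 3  7.529856 5.727565 3.255032 12.430543
#> 2  8.511366 5.112382 2.905418 13.866892
#> 4 10.086552 6.003337 3.411756 23.573853

truth_table(scene$truth)[order(truth_table(scene$truth)$V_true),
                         c("P_true", "L_true", "V_true")]
#>     P_true   L_true    V_true
#> 2 6.316001 4.298420  6.167517
#> 4 7.476682 5.910563 12.718238
#> 1 8.396846 5.206971 13.797857
#> 3 9.999327 6.149911 23.830685
```

Perimeters recover within ~1–2 % and volumes within a few percent on
noise-free 3 cm scenes. Each recovered row corresponds to the truth row
with the matching volume (instance order differs). The same functions accept
polygons from any external model via VIA 1.x JSON (`read_via_json()`) or
labeled mask grids (`masks_to_instances()`).

`run_pipeline(pipeline_config())` runs the whole chain — 150 patches,
80/20 split, four subsets (3 cm and 13 cm, NDVI/GNDVI) — and writes the
metrics tables, per-tree measurements and accuracy summary as CSV.
`reproduce_reference_tables()` recomputes the reproduced study's printed
detection metrics, volumes and accuracies from their printed inputs and
reports pass/fail per cell.

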
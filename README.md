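# sightshed

Quantifies the **shielding effect** of a 3D environment on an observed body,
from a terrestrial-LiDAR point cloud. Ecologists studying concealment,
predator–prey sightlines, or the "landscape of fear" need to know not whether
*a location* is visible, but how much of *an animal of a given size* is
visible from an observer — and how terrain changes that.

The observed is simplified to its minimum enclosing rectangle (width `w`,
height `h`), stood vertically on the ground at azimuth θ and distance `i`
from the observer, perpendicular to the sight direction. Every cloud point
between observer and target is projected along the line of sight onto the
rectangle, the rectangle is rasterized at a chosen resolution, and the
visibility index is

```
V(θ, i) = (N − n(θ, i)) / N × 100 %
```

with `N` the rectangle's pixel area and `n` the pixels occupied by projected
points; `100 − V` is the shielding effect. A polar survey collects `V` over a
grid of directions and distances (36 × 80 = 2880 samples by default), and
`V = a + b·ln(i)` summarises the decay of visibility with distance.

Two scenarios:

* **normalized** — ground flattened to height 0; only above-ground structure
  occludes, and `V` is non-increasing in distance (cumulative occlusion);
* **non-normalized** — altitudes kept; the projection volume tilts with the
  elevation angle `Ω = arctan((z_target − z_observer)/i)`, so terrain relief
  can occlude the target or expose it (visibility *deviation*, which grows as
  the observed gets smaller).

The pipeline: ground classification → height normalization (optional) →
ground densification ("encryption", so sparse ground returns still block the
pixels they should) → projection → binary occlusion image → visibility table.
Everything is testable offline through a seeded synthetic-scene generator
with ground-truth labels.

## Worked example

```r
library(sightshed)

scene <- make_scene(scene_spec(extent = 40, terrain = "sinusoid", amplitude = 1,
                               wavelength = 20, n_trees = 60, ground_spacing = 0.3,
                               crown_points = 800, seed = 7))
scene
#> <point_cloud> 68089 points
#>   x: [-19.996, 19.896]  y: [-20.358, 20.346]  z: [-1.000, 7.770]
#>   labels: none

cfg <- survey_config(observer(0, 0, 0), w = 1.5, h = 2, resolution = 0.02,
                     max_distance = 15, distance_step = 0.5)
sv <- shield_survey(scene, cfg)     # classify -> normalize -> densify -> survey
sv
#> <visibility_survey> normalized scenario: 1080 samples (36 directions x 30 distances)
#>   visibility: min 92.3%, median 98.9%, max 99.8%

fit_log_model(sv)
#> visibility = 0.994 -0.006 log(distance)   (fractions; R2 = 0.167, n = 1080)

head(as.data.frame(sv), 3)
#>   theta distance visibility n_occupied n_total
#> 1    10      0.5         99         75    7500
#> 2    10      1.0         99         75    7500
#> 3    10      1.5         99         75    7500
```

Each record says: at azimuth θ (degrees counterclockwise from +x) and
distance `i`, `n_occupied` of the rectangle's `n_total` pixels are blocked by
projected environment points, so the animal-sized target is
`visibility` % visible. In this young open stand the 1.5 m × 2 m target
stays ≥ 92 % visible within 15 m and the fitted log-slope is shallow
(−0.006 per log-metre); denser canopies and longer distances steepen it.
`write_table()` exports the CSV, `write_occlusion_image()` the per-sample
binary images, and `deviation_between()` compares the two scenarios — on the
shipped ridge scene (`canonical_ridge_scene()`) terrain relief exposes up to
~51 percentage points of a 0.5 m target but under 4 of an 8 m one.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/sightshed.R synth --out scene.ply --seed 42 --n-trees 60
Rscript inst/cli/sightshed.R survey --cloud scene.ply --out vis.csv \
    --x0 0 --y0 0 --w 1.5 --h 0.5,2,4,8 --resolution 0.02
Rscript inst/cli/sightshed.R fit --table vis_h2.csv
```

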
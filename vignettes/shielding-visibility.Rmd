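---
title: "Quantifying the shielding effect of 3D environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the shielding effect of 3D environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sightshed)
```

## The problem

How well can an observer — a predator, say — see an animal standing `i` metres
away in a forest? Terrestrial laser scanning reconstructs the environment as a
3D point cloud, and **sightshed** turns that cloud into a visibility index for
an *observed body of explicit size*: the animal is simplified to its minimum
enclosing rectangle (width `w`, height `h`, tail excluded), stood vertically on
the ground and perpendicular to the horizontal sight direction. Every cloud
point lying between observer and target is projected along the line of sight
onto the rectangle, the rectangle is pixelated at a chosen resolution, and

$$V_{\theta,i} = \frac{N - n_{\theta,i}}{N} \times 100\,\%$$

where $N$ is the rectangle's pixel area and $n_{\theta,i}$ the number of
pixels occupied by projected points. $100 - V$ is the shielding effect of the
environment on the observed at azimuth $\theta$ and distance $i$. A polar
survey collects $V$ over a grid of directions and distances around the
observer, and a logarithmic regression summarises the decay of visibility
with distance.

Two scenarios are supported:

* **normalized** — ground points are flattened to height 0 and every other
  point is replaced by its height above ground. Only above-ground structure
  occludes; occlusion is purely cumulative, so along any direction $V$ is
  non-increasing in $i$ (more points can only enter the projection volume as
  the target recedes, never leave it).
* **non-normalized (terrain-preserving)** — altitudes are kept. The
  projection volume is tilted by the elevation angle
  $\Omega = \arctan\!\big((z_{\theta,i} - z_0)/i\big) \in (-90^\circ, 90^\circ)$
  between the observer's ground point and the target base, its vertical band
  running between $z = z_0 + \tan(\Omega)\,s$ and $z = z_0 + \tan(\Omega)\,s + h$
  along the sight axis $s$. Projected heights are corrected as
  $v = z + \tan(\Omega)\,d - z_{\theta,i}$, with $d$ the horizontal distance
  from the point to the target base line. Terrain relief can now occlude the
  target or, equally, expose it — visibility may *increase* with distance
  (a visibility deviation).

On level terrain $\Omega = 0$ and the second scenario reduces exactly to the
first applied to the height-shifted cloud; this equivalence is asserted in the
test suite.

## The pipeline and its parameters

`shield_survey()` runs classify → (normalize) → densify → survey:

| parameter | default | meaning |
|---|---|---|
| `w`, `h` | 1.5 m, 2 m | rectangle of the observed body |
| `start_angle`..`end_angle`, `angle_step` | 10°–360°, 10° | azimuths (counterclockwise from +x) |
| `max_distance`, `distance_step` | 40 m, 0.5 m | distance gradient |
| `resolution` | 0.005 m | pixel size; 1.5 m × 2 m → 300 × 400 px |
| `ground_cell`, `ground_tol` | 1 m, 0.15 m | ground classification |
| `densify_spacing` | = `resolution` | ground "encryption" grid |

The default design samples 36 directions × 80 distances = 2880 rectangles.
The azimuth convention (degrees counterclockwise from the +x axis) is a free
choice: all outputs are invariant under rotation of the scene, which the test
suite checks to 10⁻⁹ m.

### Ground classification

Ground returns are identified with a grid-minimum classifier: the lowest
point of each half-cell of a `ground_cell` grid is taken as a
minimum-surface vertex; a vertex deviating from the median of its 3×3
neighbourhood by more than max(1 m, `ground_cell`) is replaced by that median
(this vetoes noise pits below the surface and plot-edge cells that contain
only canopy, while leaving crests of curved terrain untouched — a plain
median pass would bias them downward by the curvature scale); the vertices
are interpolated into a continuous reference surface; and points within
`ground_tol` of it are labelled ground. Points of vegetation that genuinely
touch the ground (stem bases) are inside the tolerance band by construction —
no height-threshold classifier can separate them — so classification quality
is assessed on points at least 0.5 m above the terrain, where the synthetic
scenes require ≥ 99 % agreement with the generator truth.

### The ground surface model

Normalization, densification and all elevation queries use one surface
model: a Delaunay TIN with piecewise-linear interpolation over the classified
ground points. Piecewise-linear interpolation is exact on planes and
reproduces its vertices, which makes it directly testable. For speed the TIN
is evaluated once onto a regular grid (cell ≈ extent/1000, at least 2 cm)
and scattered queries are answered by bilinear interpolation from that grid;
bilinear interpolation of plane-sampled nodes is still exact on planes. To
avoid holes in boundary grid cells that straddle the convex hull, the
triangulation is augmented with eight ghost vertices placed well outside the
plot on the global least-squares plane of the ground — for planar terrain
the ghosts are coplanar with the data, so exactness is unaffected, and for
curved terrain their influence is confined to the hull margin. Small query
batches (≤ 4000) bypass the grid and evaluate the TIN directly.
Ground sets above 40 000 points are decimated to ~30 000 triangulation
vertices (one median-height point per decimation cell) before the TIN is
built: triangulation cost grows steeply with the vertex count while terrain
information saturates long before, and a densified cloud must never feed its
millions of interpolated points back into the surface model.
Queries beyond the hull fall back to the nearest ground point up to 2 m out;
farther queries are treated as out of coverage (surveys record such samples
as `NA` and continue).

Ground returns are sparse relative to the raster: a ground surface that
should block a pixel may simply have no return in it. `densify_ground()`
therefore interpolates extra ground points on a grid, by default at the
raster resolution so every pixel the ground can block is occupied. The
survey densifies only the sampled disc (`max_distance` + `w` around the
observer).

### Raster conventions

Pixel intervals are half-open with ties to the lower index; `v = h` falls
outside the rectangle and is discarded; a non-integer `w/resolution` rounds
the pixel count up, the partial band counting as a full pixel so that the
pixel total and the raster size agree. One projected point occupies exactly
one pixel — closing surface gaps is the job of ground densification, not of
point splatting. The vertical slab bounds are inclusive: a strictly
normalized ground plane sits at exactly `z = 0`, and excluding the boundary
would silently discard the entire (densified) ground. Points at the observer
(`s = 0`) and on the target plane (`s = i`) are excluded — the observer is
not an obstacle and the observed does not occlude itself. The lateral
projection coordinate `u` is positive to the left of the sight direction
(sight along +x gives `u = y − y₀`); the choice only mirrors the occlusion
image and cancels from every visibility value.

## The logarithmic visibility–distance model

`fit_log_model()` regresses visibility *as a fraction* on the *natural*
logarithm of distance, `V = a + b ln(i)`. Fraction scale and natural log are
the package's reading of fitted intercepts near 1.0 in field practice; the
fitted object reports named `intercept` and `slope` so no ambiguity about
coefficient order can arise. Noiseless log-generated data must be recovered
to 10⁻⁹ and noisy data (σ = 0.05) within three standard errors — both are
acceptance tests.

`deviation_between()` compares matched surveys of the two scenarios
(`V_non-normalized − V_normalized`, percentage points) and reports the peak
per direction; `monotonicity_violation()` measures the excess of a
visibility sequence over its running minimum — identically zero in any
normalized survey, and a detector of terrain-induced deviation otherwise.

## Synthetic scenes

`make_scene()` emulates a scanned forest plot: terrain sampled on a jittered
grid (jitter ≤ half the spacing, so worst-case ground gaps are bounded and
densification behaviour is reproducible), trees with cylindrical stems and
uniform-in-ellipsoid crowns (the simplest crown model with realistic
porosity), opaque walls, and uniform low shrub layers. Every point carries a
generator-truth label and height above terrain, so classification,
normalization and densification can be scored exactly. Scenes are
deterministic given their seed.

What the generator does *not* emulate: occlusion-aware sampling (a real
scanner sees only first returns along each beam), beam divergence, foliage
clumping, and registration noise. Passing tests therefore demonstrate the
correctness of the geometry and the qualitative terrain phenomenology, not
sensor realism.

### The canonical ridge scene

`canonical_ridge_scene()` fixes the terrain-relief test case: the observer
stands on a ~4.2 m knoll, a 2 m Gaussian ridge crosses the sight line 10 m
out, the far field is flat, and a dense shrub band 0.25–0.55 m above ground
covers the ridge crest. In the normalized scenario the shrub band occludes
the bottom 0.25–0.55 m of any target beyond the ridge. In the
terrain-preserving scenario the downhill elevation angle drops ridge and
shrubs below the tilted projection band at far distances, exposing the
target: a positive visibility deviation. Because the newly exposed band has
fixed physical depth (~0.3 m), its share of the rectangle scales as 1/h:
large at h = 0.5 m, about min(0.3, h)/h at the peak, and below ~4 percentage
points at h = 8 m — the size-dependence of terrain-induced deviation that
the framework is meant to expose. The acceptance test asserts a strictly
decreasing peak *exposure* deviation (the largest visibility increase) over
h ∈ {0.5, 2, 4, 8} m, nonzero at 0.5 m and at most 5 pp at 8 m. The scene
also exhibits the opposite-signed deviation: at intermediate distances,
while the elevation angle is still shallow, the ridge itself shadows a
~0.7 m band of the target that the normalized scenario ignores. That
occlusion deviation follows the same 1/h scaling (≈ −72, −36, −18, −9 pp),
and both signs together are what "terrain-induced visibility deviation"
means here.

## Problem sizes

The test suite and the acceptance script choose desk-scale conditions: survey
rasters of 0.02–0.05 m on plots of 12–90 m, ground spacing 0.15–0.5 m, and a
90 m acceptance forest of 280 trees (mean height 5.05 m) with a shrub
understory, surveyed on the full 36 × 80 polar design in both scenarios at
0.02 m resolution with 0.04 m ground densification. The 0.005 m default
resolution is practical for single targets and field-scale batch runs; the
coarser settings keep the shipped analyses reproducible in minutes without
changing any behaviour being tested.

## Known limitations

* Projection is orthographic along the horizontal sight direction, as the
  framework defines it — not a perspective projection from the observer's
  eye; there is no depth ordering, only binary occupancy.
* Animal visual acuity is out of scope; the occlusion image (written with
  `write_occlusion_image()`) is the reserved interface for grafting an
  imaging model on top.
* LAZ-compressed clouds are not read; decompress to LAS first.
* The ground classifier is a simple grid-minimum design adequate for the
  framework's needs; heavily overhanging terrain or dense near-ground
  vegetation will misclassify points within the tolerance band, which then
  flatten into the ground at normalization.
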
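---
title: "Rendering and analysing compound-eye vision with compeye"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rendering and analysing compound-eye vision with compeye}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compeye)
```

## The model

An arthropod compound eye is a patchwork of ommatidia: self-contained optical
units, each with its own lens and photoreceptor cluster, spread over a curved
3D surface. Because every ommatidium images the world from its own position,
a compound eye is a *multi-viewpoint* sensor; a single projective camera
cannot reproduce it. `compeye` therefore renders each ommatidium
independently by ray casting.

An ommatidium is described by four quantities: a position (mm, eye-local
frame), a unit viewing axis, a full acceptance angle $\Delta\rho$, and a
focal offset that displaces the ray origin along the axis. Its output colour
is the average light collected over its *sampling domain*, a cone of
directions around the axis weighted by a Gaussian whose full width at half
maximum equals the acceptance angle:

$$\sigma = \frac{\Delta\rho}{2\sqrt{2\ln 2}}.$$

Rather than casting a fixed, weighted fan of rays (the classical static
pattern), the sampler draws the angular deviation of each ray from the axis
as $|N(0, \sigma)|$ (truncated at $\pi$ by resampling) with uniform azimuth,
and averages equally weighted samples. Static patterns alias structured
scenes — `fixture_rings_plane()` contains three concentric rings which a
concentric static pattern misses entirely, returning pure white — whereas
stochastic redrawing each frame converts structured aliasing into unbiased
frame-to-frame noise, so averaging frames is the same estimator as raising
the per-frame sample count. `sampler_config(frames_to_average = k)` exploits
this identity directly.

The Gaussian could alternatively be read as a *weight* on directions drawn
uniformly in solid angle within the cone; this measure is implemented behind
`measure = "weighted_cone"` for sensitivity checks. The default applies the
Gaussian to the angular deviation itself, which reproduces the half-normal
deviation statistics the test-suite checks by goodness of fit.

Rays intersect triangle-mesh scenes through a watertight ray-triangle test
wrapped in a binned-SAH bounding-volume hierarchy (leaf size 4). The
accelerated path is required to return *identical* hits to brute force —
equal-distance ties break towards the lowest (mesh, triangle) index on both
paths — which the suite verifies on 10^4 random rays per fixture. Hits
closer than $10^{-6}$ mm are discarded as self-intersections. Materials are
unlit: a base colour, or a bilinear texture lookup when the mesh carries uv
coordinates. There is no recursion — no shadows, reflection or refraction;
one ray returns one surface colour or the scene background.

## Reproducible randomness

Every random draw comes from a counter-based stream (a splitmix64 chain)
keyed by `(seed, frame, ommatidium identity, sample index)`, where the
identity is a hash of the ommatidium's own parameters. Renders are therefore
bit-reproducible for a fixed seed, independent of evaluation order, and an
ommatidium keeps its sampling stream when an eye description is reordered or
when frames are rendered one at a time instead of batched.

## Scenes and eyes on disk

Scenes are glTF 2.0 files (`load_gltf()`/`save_gltf()`): triangle meshes,
flat or PNG-textured materials, and cameras. glTF units are treated as
millimetres. Compound cameras are ordinary glTF cameras whose reserved
`extras` block carries `compound-eye: true`, `compound-structure:` (an eye
CSV path resolved relative to the glTF file) and an optional
`compound-projection` hint; traditional perspective, orthographic and
equirectangular-panoramic debug cameras are also supported. The package's
pose convention is +z forward / +y dorsal; glTF's -z-forward cameras are
converted on load and write. Eye descriptions live in CSV files with the
header `px,py,pz,dx,dy,dz,acceptance,focal_offset[,label]` — positions in
mm, angles in radians; the column set is this package's own, since only the
mechanism (camera extras plus a linked CSV) is standardised.

Three self-contained fixture scenes support the analyses: the concentric
rings plane (aliasing), a closed black/white-checkered lab box
(high-contrast sampling noise, in the spirit of insect-cognition arenas),
and a white world containing a small black sphere (localisation).

## Eye designs

`make_spherical_eye()` places ommatidia on a Fibonacci sphere lattice with
radial axes — deterministic and near-uniform (nearest-neighbour spacing CV
below 0.25). `make_acute_zone_eye()` builds a horizontal acute zone:
acceptance angles ramp smoothly (smoothstep) from `acute_angle` inside the
band to `base_angle` at the dorsal/ventral poles, and latitude density
follows $\cos(\mathrm{lat})/\Delta\rho(\mathrm{lat})^2$ via a deterministic
inverse CDF, so local ommatidial spacing tracks the local acceptance angle.
That coupling is this package's choice (the qualitative description —
denser, sharper ommatidia along the horizon — does not pin down a density
law); it is what makes the design cover the full sphere without
oversampling, which the coverage checks quantify against a homogeneous
small-angle eye that leaves polar blind spots.

`make_paired_eye()` is a synthetic bilateral eye: two mirrored Fibonacci
caps on spheres at $\pm$`separation`/2, radial axes, left/right labels, and
a field of view limited to `fov_halfangle` about +z. It stands in for
scanned real eye surfaces, which are deliberately not shipped; everything
the experiments need from a "real" design is a genuine 3D viewpoint spread,
bilaterality and a bounded field of view. `collapse_to_split()` and
`collapse_to_single()` produce the classical simplifications that discard
the surface (two viewpoints) or all geometry (one viewpoint).

## Projections

The raw ommatidial view — one RGB triple per ommatidium, in eye order — is
the native output and the recommended model input (`export_vector()`).
For human viewing, `project_orientation_voronoi()` draws the equirectangular
spherical Voronoi image: each pixel centre maps to a direction and takes the
colour of the angularly nearest axis (ties to the lowest index), evaluated
per pixel, which is mathematically the Voronoi partition without polygon
construction. `project_position_voronoi()` assigns instead by the direction
from the position centroid to each ommatidium (the centre point is this
package's choice) and coincides with the orientation-wise map for spherical
radial eyes. Like every equirectangular map these projections inflate the
poles — a polar ommatidium's pixel share exceeds its solid-angle share (a
property the suite asserts numerically) — so quantitative comparisons should
use the vector output, not projected images.

## Sampling-noise calibration

Because sampling is stochastic, a static viewpoint yields slightly different
colours each frame. The per-ommatidium spread is measured as the standard
deviation over frames of the Euclidean distance in RGB space from the
per-ommatidium mean, expressed as a percentage of the maximum colour
difference (the length of the all-255 vector). Spread concentrates at
high-contrast edges and decays as $N^{-1/2}$ in the per-frame sample count
$N$ (the suite regresses the log-log slope to $-0.5 \pm 0.1$).

Ommatidia with wider cones need more rays, so spreads are compared after
normalising to one steradian of coverage. `normalise_sd()` computes
$\mathrm{SD} \cdot \sqrt{\Omega/1\,\mathrm{sr}}$ with
$\Omega = 2\pi(1 - \cos(\Delta\rho/2))$: since SD scales as the inverse
square root of the sample count, this is the spread an ommatidium covering
one steradian would show at the same *ray density*, and a fixed threshold on
it corresponds to a fixed number of rays per steradian regardless of the
eye. A scene of doubled contrast variance then needs twice the rays per
steradian to meet the same threshold, which matches how high-contrast
environments behave. Plain division by $\Omega$ (spread per steradian) is
kept as `method = "per_steradian"`; it was rejected as the default because
for realistic acceptance angles of a few degrees ($\Omega \sim 10^{-3}$ sr)
a 1% threshold would demand $10^7$-plus rays per ommatidium — no sampler
operates there.

`calibrate_sample_count()` doubles $N$ until the most deviant ommatidium's
normalised spread falls below the threshold (default 1%, 1000 frames, both
configurable), then bisects to the minimal satisfying count. The spread
measured over $F$ frames is an estimate with relative standard error
$\approx 1/\sqrt{2F}$, so accepting a count whose estimate sits exactly at
the threshold would leave the true spread above it half the time; the search
therefore targets the effective level
$\mathrm{threshold}\cdot(1 - 2/\sqrt{2F})$, two standard errors inside,
which is what makes fresh-seed re-measurements of the accepted count respect
the nominal threshold. Because visual
complexity varies across an environment, `variance_map()` scans a pose grid
and `find_hotspot()` returns the worst pose; calibrating there bounds the
spread everywhere, which the suite re-measures at random poses within a 1.2
safety factor that covers estimator noise at 150-1000 frames.

## The localisation benchmark

Eye designs with different surfaces and ommatidial counts cannot be compared
image-to-image, so the package compares them through a proxy task: localise
a 2 mm matte black sphere in a white world from a single view.
`generate_dataset()` moves the eye (fixed forward-facing orientation — the
task needs no rotation augmentation and none is used) uniformly through a
50 mm cube centred on the sphere, rendering one view per pose and pairing it
with the sphere's relative offset. Views are single-channel (mean of RGB) as
the world is black and white. The "50 mm" sampling volume is read as a cube
of side 50 mm, consistent with the 2 mm target scale; it is configurable.

Inputs and outputs are z-scored per dimension (constant dimensions are
flagged and passed through). The localiser is an MLP with hidden layers of
1000 and 256 rectified-linear units and a linear 3-unit output, trained by
plain batched SGD (batch 64) on the mean per-sample L1 loss — the sum of
absolute errors over the three axes. Weights are He-uniform. The learning
rate is a free choice (no canonical value exists for this recipe): the
package defaults to a constant 0.01, selected because at the desk scales
used here (20k pairs, 30 epochs) 0.001 leaves the validation trace still
falling steeply at the last epoch, i.e. visibly under-converged, while 0.01
converges and remains stable; both are plain-SGD textbook values and the
parameter is exposed.

`error_volume()` evaluates the trained model on a regular lattice spanning
the cube, rendering views live, and records the per-cell L1 error in mm;
`difference_volume()` compares designs cell-wise and `top_down_map()`
reduces over z (mean — the reduction is a documented choice) for display.
Cells are classed in- or out-of-field by whether the sphere direction lies
within one acceptance angle of some ommatidial axis. The structural
expectations at desk scale — in-field error well below the no-information
baseline of predicting the cube centre, and the blind region behind the eye
pair carrying the highest error — are asserted by the acceptance suite with
a 200-ommatidium paired eye, 20,000 pairs and 30 epochs.
`run_design_comparison()` wires the whole pipeline for the real/split/single
designs with shared poses across arms; its defaults (2000 pairs, 10 epochs,
7^3 lattice) are a smoke scale, with the larger settings exposed.

## Numerical choices and scales

* Sample means use an all-equal fast path, so a scene whose every surface
  and background share one colour renders to exactly that colour at any
  sample count — the constant-scene invariant holds to the bit.
* Axis vectors within $10^{-3}$ of unit norm are renormalised; anything
  further is rejected with its row number (format rounding is tolerated,
  corrupt rows are not).
* Degenerate triangles (relative area below $10^{-14}$) are excluded from
  intersection. Icospheres subdivide until the chord error is under 1% of
  the radius, bounding geometric error in the occlusion tests.
* Equal-distance intersection ties and equal-angle Voronoi ties both break
  towards the lowest index, making oracle comparisons exact.
* 8-bit image export quantises with round-half-to-even; all internal colour
  is double precision in [0, 1].
* Default problem sizes in the test-suite (200-ommatidium eyes, 1000-frame
  calibrations, 20k-pair training runs, 10^4-ray oracle checks) were chosen
  as the smallest scales at which each property is stably measurable; all
  are package parameters, not limits.

## What the synthetic fixtures do and do not show

The fixtures emulate the *structure* of experimental scenes — high-contrast
patterns, a small dark target, closed arenas — with exactly known geometry,
which is what makes closed-form oracles possible. They do not contain
natural-scene statistics (broadband textures, depth complexity, lighting
variation), spectral or polarisation channels, or photoreceptor dynamics;
the renderer models the optical acceptance cone only, and transduction is
explicitly out of scope. Passing tests therefore certify the sampling,
intersection and calibration machinery and the comparison methodology — not
ecological validity of any particular eye model. Real scanned eye geometries
can be supplied as eye CSVs whenever available.

## Known limitations

* No GPU path: throughput is minutes per million-ray analysis, not
  real-time; the design favours exactness and reproducibility.
* glTF support covers the subset the package writes (triangles, flat/PNG
  textured materials, TRS nodes, cameras); strided buffer views, sparse
  accessors, Draco compression and skinning are rejected.
* Only the `extras` key spelling used by `save_gltf()` is recognised for
  compound cameras.
* The localisation MLP is a comparison instrument, not a model of insect
  neural processing; architectures that respect the eye's surface topology
  (e.g. graph networks) are out of scope.
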
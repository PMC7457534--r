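---
title: "Models and methods behind phenomesh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenomesh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomesh)
```

`phenomesh` analyses triangle-mesh plant models produced by turntable
multi-camera photogrammetry and, because raw imagery from such rigs is
rarely redistributable, ships a fully controlled synthetic counterpart of
the acquisition. This vignette explains the models, the parameters that
matter, the numerical choices, and what the synthetic experiments do and do
not demonstrate about real data.

## Conventions

All coordinates are millimetres with +Z the zenith and the soil plane at
z = 0. Leaf areas are reported in cm², every other length in mm. The *mesh
inclination angle* of a face is the zenith angle of its normal folded into
[0°, 90°]: 0° for a horizontal face, 90° for a vertical one. Folding makes
the statistic independent of which lamina side a normal happens to point
to, which matters because thin leaves are reconstructed from both sides and
no consistent orientation can be assumed.

## The acquisition geometry

The rig model is ten cameras on a vertical arc, 12° apart starting at the
zenith (so camera C2 sits at a viewing zenith angle, VZA, of 12° and C6 at
60°), each about 1 m from the scene centre on the rotation axis. The
turntable advances 9° per frame and each camera fires once per stop, 41
frames per full rotation; the first and last frame coincide in pose, so
consecutive-visibility runs are computed on the cyclic sequence of 40
distinct poses and a face visible at every pose is credited with all 41
frames. Perspective image formation is deliberately reduced to ray
geometry: the lens and sensor parameters of a real rig only determine that
a ~1 m range covers the scene, and image formation itself is out of scope.

Visibility is computed by casting a ray from each face centroid to the
camera position of each pose (rotating the camera by −θ about Z is
equivalent to rotating the plant by +θ) and testing occlusion against every
other face with the Möller–Trumbore intersection test (compiled via Rcpp; a
segment/AABB slab test prunes candidates). Two details encode what a
feature matcher can actually use:

* **Both lamina sides count.** Leaves are modelled as single-layer
  surfaces; back-face visibility is real visibility.
* **Foreshortening cutoff** (`max_incidence`, default 70°): a face whose
  normal makes more than this angle with the viewing ray is foreshortened
  to a sliver and yields no matchable texture, so it does not count as
  seen. This is the mechanism by which near-horizontal cameras fail on
  planophile leaves: at a VZA beyond ~70° a flat leaf is never usably
  imaged, and its model ends up undetected. The 70° default is a
  view-planning-style rule of thumb; it is exposed on `camera_rig()` and
  the qualitative VZA ranking is insensitive to moderate changes.

## The reconstruction fidelity model

Which surface patches survive the SfM pipeline, and how precisely they are
placed, is governed by `noise_model()`:

* **Consecutive-frame rule** (`n_min`, default 9): a vertex must stay
  visible for at least `n_min` consecutive frames for the feature matcher
  to track it; a face is reconstructed only when all three of its vertices
  qualify. The field rule of thumb this encodes ("more than 9
  consecutive images") is ambiguous between ≥ 9 and ≥ 10; we default to
  the inclusive reading, and the parameter is configurable.
* **Parallax noise** (`sigma0` = 0.05 mm·rad, `theta_min` = 0.01 rad,
  `sigma_max` = 5 mm): a reconstructed vertex is displaced along its mean
  viewing ray by a zero-mean Gaussian with
  σ = min(σ₀ / max(θ, θ_min), σ_max), where θ is the *widest* angle between
  the viewing rays across the vertex's longest visible run — the widest
  triangulation baseline. Taking the widest pair rather than the run's
  endpoints matters only for closed (full-circle) runs, where the endpoint
  pair degenerates to two nearly identical poses; for partial arcs up to a
  half rotation the two definitions coincide. A camera on the rotation
  axis never changes its viewpoint relative to the plant, so θ = 0, the
  depth is unconstrained, and every vertex saturates at σ_max: this is the
  nadir camera's characteristic failure, and the reason its model turns
  almost entirely unstable rather than undetected.

The σ constants are free parameters of the simulator with stated defaults
(σ₀ chosen so that mid-arc cameras produce sub-0.1 mm noise at a 1 m range,
σ_max large enough to destroy local face orientation); every conclusion
drawn from them in the tests is ordinal (which cameras rank where), never
numeric.

## Region segmentation and optimum-VZA selection

`cumulative_area_curve()` accumulates detected face area over inclination
angle; `determine_threshold()` reads off the smallest angle at which the
curve reaches the directly measured organ area (on a fine hemisphere the
curve reproduces the analytic spherical-cap law 1 − cos φ, which is the
package's main numerical check of this machinery). `classify_regions()`
splits a model into stable / unstable / undetected parts at a threshold of
45° by default. Three choices the verbal definition leaves open are
fixed as follows:

* the three fractions share the denominator *detected + undetected* so
  they partition 1;
* *undetected* is an area deficit against the direct measurement; when
  noise inflates the detected area beyond it, undetected is 0 and the
  excess simply inflates the other two parts;
* faces exactly at the threshold count as stable (the verbal definition
  assigns "larger than" to unstable and "less than" to stable, leaving
  ties unassigned).

`select_optimum_vzas()` keeps cameras with stable ≥ 95%, unstable ≤ 2.5%
and undetected ≤ 2%. These criteria are descriptive of a well-behaved rig
rather than prescriptive, so they are configuration, not constants. On the
synthetic single-leaf sweep the selection reproduces the expected band:
C2–C6, i.e. 12°–60°.

## The synthetic plant

`generate_leaf()` builds a lamina as a triangulated elliptic outline
(optionally jittered radially and drooped parabolically along the midrib),
tilted to a prescribed tip–base elevation and azimuth. This family was
chosen because it is the simplest in which all five leaf traits — area,
length, width, inclination, attachment — are independently controllable;
ground truth is computed from the generated geometry itself (area by exact
face summation, length from the tip/base landmark vertices, and so on), so
trait recovery can be asserted without circularity. The default
`plant_spec()` describes a bushy six-leaf succulent: leaf lengths 49.1,
52.4, 58.2, 55.2, 42.9, 42.9 mm, widths 34.3, 33.8, 42.6, 44.2, 28.9,
30.0 mm, inclinations 20°, 10°, 3°, 5°, 10°, 10°, three internodes of 18,
16, 18 mm (radii 1.95, 1.75, 1.5 mm), and a plant top at 98.7 mm. Because
the measured stem ends at 52 mm while the plant top is 98.7 mm, the
difference is realised as a thin apical stalk (label `apex`) above the last
node — the natural reading for a succulent that bolts an inflorescence —
which counts for plant height but not for internode traits. A 27 × 27 cm
soil plate at z = 0 provides the occlusion from below that a real rig's
table introduces; fiducial markers are not modelled because registration is
exact in the simulator.

Leaf azimuths (0°, 180°, 90°, 270°, 45°, 225°) and two-leaves-per-node
attachment heights are the package's own choice of a realistic rosette that
keeps self-occlusion moderate. The generator is closed-form except for the
optional outline jitter, which is seeded.

## Trait extraction

The extractors follow the field's operational definitions: plant height is
the top of the non-soil mesh above z = 0; leaf length is the straight
tip–base chord (not a surface geodesic — the definition speaks of a
connecting *line*); leaf width is the extent perpendicular to the tip–base
axis after projection onto the best-fit lamina plane (the 2-D phrasing of
the manual measurement leaves out-of-plane handling open; the planar
projection is the stable choice); leaf inclination is the elevation of the
tip–base chord, in [0°, 90°]. Internode height is the node-to-node
distance; internode width is twice the median radial distance of the
mid-height slab (± 0.5 mm) vertices from the fitted axis point, with the
axis point per slab obtained by an algebraic least-squares circle fit —
a centroid would drift towards the detected side when only an arc of the
circumference was reconstructed, which is exactly the situation in partial
models. An internode with no detected slab is reported NG (missing), and NG
propagates through the error tables, whose per-trait averages then cover
the remaining organs only.

Tip and base are re-detected from the leaf boundary (base = boundary vertex
nearest the attachment, tip = boundary vertex farthest from the base) only
when the generator's landmark vertices are absent from a reconstruction;
wherever exact landmarks exist they are used, keeping the heuristic out of
accuracy statements.

## The two fusion strategies

*Method 1* (`merge_method1()`) unions the detected face sets of the
per-VZA partial models and fuses shared vertices by inverse-variance
weighting (weights 1/σ² from the simulator's known noise scales), which
reduces to plain averaging for equal σ and gives the expected σ/√k for k
equal observations. Duplicate partials from the same camera are counted
once, making the merge idempotent. Registration across models is exact
because the simulator shares one scene frame; real rigs achieve this with
coded targets, which are out of scope.

*Method 2* (`joint_model_method2()`) is an *emulation*: the mechanism by
which a pooled reconstruction fails — one camera per 12° vertically gives
too little vertical overlap for features seen from a single camera only —
is known, but no algorithmic rule for it is published. We encode it as a
co-visibility requirement: a face must both pass the consecutive-frame rule
for some camera and be visible from at least two distinct cameras. This
makes Method 2's detected set a subset of Method 1's by construction, so
every comparison between the methods in the tests is ordinal (subset
relations, NG counts), never a numeric claim about real pooled SfM.

`completeness()` reports each organ's detected share of its reference area.
Detected faces contribute their *true* (unperturbed) areas, making
completeness a pure coverage measure that is monotone under adding cameras
— reconstruction noise can neither inflate nor shrink it.

## Error statistics and rounding

`error_percentage()` and `error_over_plant_height()` implement the two
relative error forms (the latter normalises by plant height so organs of
different sizes are comparable); `inclination_error()` is the absolute
degree difference. Reported values are rounded half-away-from-zero — base
R's round-half-even would turn 1.875% into 1.8% where the reporting
convention prints 1.9% — to one decimal by default, two where a table cell
demands it. Error tables keep full precision internally and expose averages
both of the unrounded errors and of the printed (rounded) entries, since
reported tables are typically averaged from their printed cells.

## Problem sizes and numerical choices

The default plant meshes at a 3 mm target edge length (~2 700 faces, ~1 500
vertices), the single-leaf sweep at 2–2.5 mm (~600–900 faces); the
spherical-cap validation uses a hemisphere with 1° colatitude bands
(~32 000 faces), below which the alignment of flat-face normals with the
45° cut biases the stable fraction by more than the 1% check allows.
Ray-segment intersection uses strict-interior barycentric tests (edge
grazes do not occlude, so adjacent faces never shadow each other) with a
1e-6 relative clearance at both segment ends; rotations are validated
orthonormal to 1e-8 and reflections rejected; degenerate faces (area ≤
1e-10 mm²) are dropped at construction with a count. Determinism: all
randomness (outline jitter, noise draws) flows from explicit seeds, with
per-camera sub-seeds so partial models are independent of the order in
which cameras are simulated; RNG state of the caller is restored.

## What the synthetic experiments show — and what they cannot

The simulator reproduces the *mechanisms* of the acquisition: visibility
and occlusion geometry, the consecutive-overlap requirement, parallax-
dependent depth precision, foreshortening. It omits photometry (texture,
specular halation, shadows), feature-matching failures unrelated to
geometry, lens distortion, registration error between per-camera models,
and surface meshing artefacts such as hole filling. Consequently, passing
tests demonstrate that the analysis chain — segmentation, threshold
determination, optimum-VZA selection, fusion, trait extraction, error
tabulation — is correct and self-consistent, and that the qualitative VZA
ranking and Method 1 ⊇ Method 2 ordering follow from the encoded
mechanisms. They do not certify numeric completeness percentages or error
magnitudes for any real rig; those depend on the omitted effects and on
the real imagery.

## Known limitations

* PLY/OBJ support covers the common geometry cases (ASCII and binary
  little-endian PLY, polygonal faces by fan triangulation, one organ label
  per face) but not textures, colours or multi-object files.
* Winding consistency within a connected component is assumed, not
  enforced; all shipped statistics are winding-proof by the normal-sign
  folding.
* The width of strongly curled leaves is a planar-projection chord; for the
  near-flat laminae modelled here the difference to a surface measurement
  is negligible, but for curled species it would not be.
* `joint_model_method2()` is an emulation of a failure mode, not a model of
  pooled bundle adjustment.
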
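---
title: "Methods: airway route planning and virtual bronchoscopy geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: airway route planning and virtual bronchoscopy geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bronchoplan)
```

# The problem

Bronchoscopy for peripheral lung lesions requires navigating a flexible
scope through a bifurcating airway tree toward a target that is usually not
visible from inside the airways. Planning support consists of (i) a map of
the airways extracted from CT, (ii) a marked target, (iii) the centerline
route from the trachea to the airway point closest to the target, and (iv)
virtual-bronchoscopy (VB) renderings along that route. `bronchoplan`
implements the computational geometry behind these steps as a headless
library plus a small CLI; everything operates in LPS (left-posterior-
superior) patient coordinates in millimetres, the DICOM convention, with
the superior direction along +z.

# The branch model and the route-to-target algorithm

The airway tree is stored as *branches*: ordered centerline positions
(proximal first), a representative radius, a generation number (trachea =
0), and parent/child links. Every branch except the trachea has exactly one
parent.

The route to a target T is computed exactly as a parent-walk:

1. scan all stored positions of all branches for the one closest to T in
   Euclidean distance (ties: smallest branch id, then smallest index);
2. collect the positions from that point to the proximal top of its branch;
3. append all positions of the parent branch, and repeat until the trachea
   top is reached;
4. reverse the collected sequence.

On a tree this parent-walk is the unique simple path from the trachea top
to the closest position, so it must coincide with a graph-search shortest
path on the position adjacency graph. That equivalence is the core
correctness property: the test suite and the acceptance script check the
full point sequences against an independent `igraph` breadth-first search
on 100 random phantom/target pairs. The route never leaves the airway; the
residual distance from the route end to the target is reported as `gap_mm`.

A junction point is stored exactly once, as the last (distal) position of
the branch proximal to it. Children start at their first non-junction
point. This keeps per-branch position sets disjoint, and routes free of
duplicated consecutive points, at the cost of a one-step gap between a
parent's distal end and each child's first stored point — the parent link
carries the connectivity.

# Stand-in airway extraction

The package deliberately does not reproduce any published airway
segmentation algorithm; it provides a simple, well-characterised stand-in
so the pipeline runs end-to-end:

* **Seeded region growing** (`segment_airways()`): the 26-connected
  component of sub-threshold voxels containing a user-supplied seed in the
  trachea. Growth is step-wise adaptive: it starts just above the seed
  intensity and relaxes the threshold in 50 HU steps up to the final
  threshold (default −500 HU). If a single step adds more than
  `max_fraction` (default 0.25) of all voxels, growth stops at the previous
  step — a leakage guard against bursting through the airway wall into the
  parenchyma. There is no automatic seed detection; the seed is an explicit
  argument (and CLI flag).
* **Skeletonization** (`extract_centerline()`): sequential topological
  thinning on the voxel lattice. A border voxel is deleted if it is a
  *simple point* for the (26, 6) foreground/background adjacency pair —
  checked with the Bertrand–Malandain local characterisation (one
  26-component of foreground in the 26-neighbourhood, one 6-component of
  background in the 18-neighbourhood adjacent to the centre) — and not a
  curve endpoint (≤ 1 foreground 26-neighbour). Candidates are processed
  in increasing distance-transform order, so the surviving curve is
  medially centred; no sub-voxel refinement is attempted, because the
  downstream consumer is the branch-topology builder. Per-point radii come
  from the Euclidean distance transform (exact squared-distance transform,
  anisotropic spacing).
* **Surface extraction** (`surface_from_mask()`): marching tetrahedra on
  the Kuhn 6-tetrahedra subdivision of each cell, which tiles space
  consistently and therefore yields watertight meshes without marching
  cubes' ambiguous-case tables. The field triangulated is not the raw 0/1
  mask but its signed Euclidean distance, box-smoothed once (3×3×3) and
  then clamped so foreground voxel centres stay strictly positive and
  background centres strictly negative. The smoothing removes the lattice
  staircase that otherwise biases surface area upward by tens of percent;
  the clamp guarantees the smoothed surface never crosses a voxel centre,
  so every foreground centre remains strictly inside the closed surface.
  On a voxelized ball at spacing r/5 the resulting area is within a few
  percent of 4πr².

# Building the branch tree from unstructured points

`build_tree()` receives an unordered centerline point set (skeleton voxels
converted to mm). The construction is:

1. link all point pairs within `connectivity_radius` (default 2× the
   largest voxel spacing — the reach of a 26-neighbourhood step);
2. keep the largest connected component (the discarded fraction is
   reported);
3. take a minimum spanning tree of the proximity graph. The raw radius
   graph contains shortcut edges (a voxel chain has i→i+2 links within the
   radius); the MST with Euclidean weights removes exactly those while
   preserving connectivity. Ties between equal-length edges are broken by a
   coordinate-derived key, making the result invariant under permutation of
   the input points;
4. nodes of MST degree ≥ 3 are junctions; maximal junction-free chains are
   branches; leaf chains with fewer than 3 own points hanging off a
   junction are pruned as skeletonization spurs (threshold configurable),
   iterating until stable;
5. the root is the branch containing the most superior endpoint (largest
   z; ties broken by largest per-point radius — the trachea is the most
   superior and widest airway), and generations are assigned breadth-first.

This module assumes nothing about how the centerline was produced; any
x, y, z (+ optional radius) table (CSV, VTP) can be imported.

# The phantom generator

`generate_airway_tree()` produces the ground truth every downstream stage
is tested against: a symmetric binary tree in which branch length and
radius scale per generation. Defaults — trachea radius 9 mm, length 100 mm,
length ratio 0.7, radius ratio 0.79 ≈ 2^(−1/3) (Weibel-like), branching
angle 35°, 20 points per branch — are anatomically plausible for an adult
human airway so that generation-dependent tube radii downstream are
realistic; all are overridable, and an optional angular jitter (with its
own seed) produces irregular trees for property tests. Children directions
are obtained by rotating the parent direction by ± the branching angle
about an axis that itself rotates 90° per generation, so consecutive
bifurcation planes alternate and the tree is three-dimensional and
self-avoiding. The trachea grows in −z from its top, matching the
anatomical convention above.

`voxelize_tree()` rasterises the tree as a union of capsules (voxel centre
within the branch radius of a centerline segment); `simulate_ct()` assigns
−1000 HU to the lumen, 0 HU to a one-voxel wall shell (every background
voxel 26-adjacent to lumen — so sub-air region growing cannot take any
26-step out of the lumen without meeting the wall), −800 HU to parenchyma
background, plus optional Gaussian noise under a fixed seed.

What the phantom does *not* emulate: lobar anatomy, asymmetric branching
ratios, cartilage texture, partial-volume effects at the wall, breathing
motion, or pathology. Tests passing on phantoms therefore demonstrate
geometric and topological correctness of the algorithms, not clinical
segmentation performance on patient CT.

# Virtual bronchoscopy geometry

* **Smoothing** (`smooth_centerline()`): moving average with the window
  clamped symmetrically at the ends (endpoints are fixed points). The
  default window of 5 points removes voxel-level zig-zag without visibly
  shortcutting bends at the phantom's point spacing. Spline smoothing was
  rejected to keep the "camera stays on the polyline" semantics exact.
* **Tubes** (`generate_tube_mesh()`): one tube per branch, swept along the
  smoothed branch centerline with a parallel-transport frame, `n_circ`
  (default 16) vertices per ring, fan caps at both ends. Each per-branch
  tube is closed and watertight (every edge shared by exactly two faces,
  Euler characteristic 2). Tube radius depends only on generation through a
  configurable map, default r(g) = 9·0.7^g mm — a monotone geometric decay
  chosen so the trachea is always the widest tube; no published
  per-location diameters were available to copy. Child tubes start at the
  child's first stored point; small gaps under the parent cap at high
  branching angles are accepted rather than blended, as they only affect
  rendering, not any measured geometry.
* **Fly-through** (`fly_through_path()`): poses are sampled by arc length
  every `step_mm` along the smoothed route, by linear interpolation — so
  positions lie on the polyline to machine precision, and the slider
  parameter p ∈ [0, 1] is linear in arc length. View directions are
  normalised central differences (one-sided at the ends). The up vector
  starts as patient anterior (0, −1, 0) projected orthogonal to the first
  tangent — an anatomically meaningful zero roll — and is carried along by
  parallel transport (rotation from each tangent to the next), then rolled
  about the view direction; a `reversed` flag traverses tip-to-trachea.
  Parallel transport guarantees no frame flips; consecutive up vectors turn
  by less than 10° per step on C¹ routes.
* **Cut planes** (`cut_planes_at()`): three planes through the current
  centerline position with normals along the patient x (sagittal), y
  (coronal) and z (axial) axes. Only the plane geometry and mesh clipping
  (`clip_mesh_by_plane()`, Sutherland–Hodgman per triangle) are computed;
  resampling CT intensities along the planes is rendering work and out of
  scope.
* **Overview camera** (`overview_camera()`): positioned on a sphere of
  radius 1.5× the tree bounding-box diagonal around the box centre —
  far enough that the whole tree fits in a 60° cone — at default elevation
  30° / azimuth 30° (anterior–superior–right), looking at the centre with
  an approximately superior up vector.

# Numerical choices and degenerate inputs

* Distance ties in `closest_centerline_point()` break to the smallest
  branch id, then the smallest position index — documented and tested.
* `camera_pose()` enforces unit vectors to 1e−9 and orthogonality to 1e−6.
* Single-point centerline sets build a one-position tree; single-point
  routes have length 0; empty masks, empty trees and out-of-volume seeds
  raise typed conditions (`bronchoplan_input_error`,
  `bronchoplan_geometry_error`, `bronchoplan_seed_error`, ...).
* All randomness (phantom jitter, CT noise) flows from explicit integer
  seeds; reruns are bit-reproducible, and the full pipeline writes
  timestamp-free JSON artifacts that are byte-identical across reruns.
* JSON artifacts round-trip numeric values at the serializer's printed
  precision (~15 significant digits); MetaImage volumes round-trip
  losslessly (float64 raw), NIfTI headers store geometry as float32.

# Problem sizes used by the tests

The test suite and acceptance script exercise phantoms of depth 0–6 for
structural properties, and voxel grids up to roughly 100×100×120 at
1.5–2.2 mm spacing (about 10⁶ voxels) for the segmentation, thinning and
topology-recovery checks — depth 3 is voxelized at half the finest branch
radius. These sizes were chosen so the full geometric pipeline, including
sequential thinning, completes in seconds per case while branch radii still
span several voxels, which is the regime the recovery guarantees need.

# Known limitations

* The segmentation stage is a stand-in: on real CT it will under-segment
  distal airways long before a state-of-the-art method would.
* The DICOM reader supports uncompressed explicit-VR little-endian,
  axis-aligned CT series only — sufficient for series this package writes
  and for simple scanner exports, not a general DICOM implementation.
* Branch radii from the distance transform are voxel-quantised; no
  sub-voxel radius estimation is attempted.
* No anatomical branch naming (RB1, LB6, ...) or lobe classification.
* Routes end at the closest centerline position; planning a wall puncture
  point toward an extraluminal target is out of scope.
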
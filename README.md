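# bronchoplan

Headless airway route planning and virtual-bronchoscopy geometry for
bronchoscopy toward peripheral lung lesions.

Navigating a flexible bronchoscope through the bifurcating airway tree is
hard: small peripheral lesions sit outside the airways and cannot be seen
from inside them, so the diagnostic yield for non-visible tumors is low
without planning support. This package implements the computational core of
a CT-based planning workflow, for researchers building or evaluating such
systems:

* **Branch model** — the airway tree as branch objects holding ordered
  centerline positions, a radius, a generation (trachea = 0) and
  parent/child links; every branch but the trachea has exactly one parent.
  Built from unstructured centerline points (`build_tree()`), serialized as
  JSON, validated (`validate_tree()`).
* **Route-to-target** — given a pinpointed target **T**, select the
  centerline position `x* = argmin_x ‖x − T‖₂` over all branch positions,
  walk from `x*` to the top of its branch, append each parent branch up to
  the trachea top, and reverse: the route runs from the trachea top to the
  point inside the bronchi closest to the target. On a tree this
  parent-walk equals the graph shortest path — the package's central
  correctness property, tested against an independent `igraph` search. The
  residual `gap_mm = ‖x* − T‖` is reported; the route never leaves the
  airway.
* **Virtual bronchoscopy geometry** — moving-average smoothed centerlines;
  synthetic tube meshes swept around them with generation-dependent radii
  `r(g) = 9·0.7^g` mm (trachea widest), watertight per branch; fly-through
  camera paths sampled by arc length with parallel-transport up vectors;
  axis-aligned cut planes (sagittal/coronal/axial) tracking the current
  centerline position; an elevated overview camera; mesh clipping by planes.
* **Stand-in extraction** — seeded region growing with a leakage guard,
  3D topological thinning to centerlines with distance-transform radii, and
  watertight isosurfaces, so the five-step workflow (import → extract →
  pinpoint → route → VB) runs end-to-end. This stage is explicitly a
  simplified stand-in, not a reimplementation of any published clinical
  segmentation algorithm.
* **Phantoms** — a generator of ground-truth bifurcating airway trees,
  voxelized lumen masks and pseudo-CT volumes (Weibel-like defaults:
  trachea 9 mm radius / 100 mm length, radius ratio 0.79 ≈ 2^(−1/3)),
  so every stage is testable without patient data.
* **I/O** — DICOM CT series (read/write, uncompressed explicit-VR
  little-endian), NIfTI and MetaImage volumes, CSV/VTP centerlines, STL/PLY
  meshes, JSON trees/targets/routes/camera paths. All coordinates are LPS
  millimetres.

## Worked example

```r
library(bronchoplan)

# 1. ground-truth phantom: depth-2 bifurcating airway tree
tree <- generate_airway_tree(phantom_params(depth = 2, seed = 1))
tree
#> <airway_tree> 7 branches (4 terminal), max generation 2, 419.2 mm of centerline

# 2. rasterize it and simulate a noisy CT
grid <- grid_for_tree(tree, spacing = 1.5)
mask <- voxelize_tree(tree, grid)
ct   <- simulate_ct(mask, noise_sd = 30, seed = 1)
ct
#> <image_volume> 61 x 108 x 150 voxels, range [-1123.5, 117.15]

# 3. stand-in extraction: region growing + thinning + tree building
seg <- segment_airways(ct, seed_point = trachea_top(tree) + c(0, 0, -4))
dice_coefficient(seg, mask)
#> [1] 1
rebuilt <- build_tree(extract_centerline(seg))
tree_topology_signature(rebuilt) == tree_topology_signature(tree)
#> [1] TRUE

# 4. pinpoint a lesion and compute the route
lesion <- target("lesion", c(33, -68, -194))
route  <- route_to_target(rebuilt, lesion)
route
#> <airway_route> 128 positions over 3 branches, 224 mm, gap to target 9.97 mm
glance(route)
#>   length_mm n_branches max_generation gap_mm
#> 1      224.          3              2   9.97

# 5. virtual bronchoscopy geometry
tubes <- generate_tube_mesh(rebuilt)
tubes
#> <tube_mesh> 3758 vertices, 7488 faces, 7 branches
cam <- fly_through_path(route, step_mm = 2)
head(cam, 3)
#>        p     x      y     z    vx    vy    vz    ux    uy    uz  roll
#> 1 0      0.395 -0.173 -1.22     0     0    -1     0    -1     0     0
#> 2 0.0093 0.395 -0.173 -3.22     0     0    -1     0    -1     0     0
#> 3 0.0185 0.395 -0.173 -5.22     0     0    -1     0    -1     0     0
```

Reading the output: the rebuilt tree reproduces the phantom's 7-branch
topology exactly and the segmentation overlaps the ground-truth lumen with
Dice 1.0; the planned route enters at the trachea top, traverses 3 branches
(generations 0→2) over 224 mm of centerline, and ends at the airway point
9.97 mm from the lesion — the distance a biopsy tool would have to bridge
beyond the airway wall. Camera poses sit on the smoothed centerline with
unit view directions (here straight down the trachea, −z) and anterior up
vectors; `p` is the position-slider parameter, linear in arc length.

`autoplot(tree)` and `autoplot(route, tree = tree)` draw coronal
projections; `run_workflow()` executes the whole pipeline and writes every
stage's artifact; `inst/cli/bronchoplan.R` exposes the same steps as shell
subcommands (`phantom`, `import`, `extract`, `pinpoint`, `route`, `vb`,
`run`).

## Vignette

`vignettes/bronchoplan-methods.Rmd` documents the algorithms and their
assumptions: the branch model and the parent-walk route, the thinning and
surface-extraction methods, the tree-building decisions (MST linking,
junction ownership, spur pruning), what the phantom generator does and does
not emulate, numerical choices, and known limitations.
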
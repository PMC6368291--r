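#' Seeded region growing of the airway lumen
#'
#' A stand-in airway extraction stage: grows the 26-connected component of
#' sub-threshold (air-like) voxels containing a seed placed in the trachea.
#' Growth is step-wise adaptive — it starts just above the seed intensity and
#' relaxes the threshold in `step_hu` increments up to `threshold` — with an
#' explosion guard: if one step adds more than `max_fraction` of all voxels,
#' growth stops at the previous accepted step. This mimics leakage-controlled
#' airway growing; it is not the published GPU segmentation algorithm that a
#' clinical system would use.
#'
#' @param ct An [image_volume()] in HU.
#' @param seed_point Length-3 mm position inside the airway lumen.
#' @param threshold Final upper intensity bound, HU; the mask is a subset of
#'   voxels strictly below it.
#' @param max_fraction Leakage guard, fraction of total voxels in (0, 1).
#' @param step_hu Threshold relaxation step, HU.
#' @return A [binary_mask()] containing the seed voxel.
#' @export
segment_airways <- function(ct, seed_point, threshold = -500,
                            max_fraction = 0.25, step_hu = 50) {
  stopifnot(inherits(ct, "image_volume"))
  if (!is.finite(max_fraction) || max_fraction <= 0 || max_fraction >= 1) {
    abort("`max_fraction` must be in (0, 1).", class = "bronchoplan_parameter_error")
  }
  grid <- ct$grid
  idx <- world_to_index(grid, seed_point)
  if (!in_grid(grid, idx)) {
    abort("seed point lies outside the volume.", class = "bronchoplan_geometry_error")
  }
  idx <- idx[1L, ]
  seed_hu <- ct$data[idx[1], idx[2], idx[3]]
  if (seed_hu >= threshold) {
    abort(sprintf("seed intensity (%.0f HU) is not below the threshold (%.0f HU).",
                  seed_hu, threshold),
          class = "bronchoplan_seed_error")
  }
  seed0 <- (idx[1] - 1) + grid$shape[1] * ((idx[2] - 1) + grid$shape[2] * (idx[3] - 1))
  steps <- seq(seed_hu + step_hu / 2, threshold, by = step_hu)
  steps <- unique(c(steps, threshold))
  total <- prod(grid$shape)
  prev <- NULL
  prev_size <- 0
  for (t in steps) {
    comp <- cpp_seed_component(as.vector(ct$data < t), grid$shape, seed0)
    size <- sum(comp)
    if (!is.null(prev) && (size - prev_size) > max_fraction * total) break
    prev <- comp
    prev_size <- size
  }
  binary_mask(grid, array(prev, dim = grid$shape))
}

#' Extract a centerline point set from a binary mask
#'
#' Reduces the largest 26-connected component of the mask to a one-voxel
#' curve skeleton by topological thinning on the voxel lattice (no sub-voxel
#' refinement), converts skeleton voxels to mm positions, and attaches a
#' per-point radius taken from the Euclidean distance transform of the mask
#' at that voxel.
#'
#' @param mask A nonempty [binary_mask()].
#' @return A tibble with columns `x`, `y`, `z`, `radius` (mm), one row per
#'   skeleton voxel; the source grid spacing is attached as attribute
#'   `"spacing"`.
#' @export
extract_centerline <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) {
    abort("mask is empty.", class = "bronchoplan_input_error")
  }
  grid <- mask$grid
  comp <- largest_component(mask)$data
  edt2 <- cpp_edt_sq(as.vector(comp), grid$shape, grid$spacing)
  skel <- cpp_skeletonize(as.vector(comp), grid$shape, edt2)
  keep <- which(skel)
  ijk <- arrayInd(keep, grid$shape)
  pos <- index_to_world(grid, ijk)
  out <- tibble::tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        radius = sqrt(edt2[keep]))
  attr(out, "spacing") <- grid$spacing
  out
}

#' Largest 26-connected component of a mask
#'
#' @param mask A [binary_mask()].
#' @return A [binary_mask()] keeping only the largest component (smallest
#'   label on ties); attribute `"discarded_fraction"` reports the dropped
#'   foreground fraction.
#' @export
largest_component <- function(mask) {
  lab <- cpp_label_components(as.vector(mask$data), mask$grid$shape)
  fg <- lab[lab > 0L]
  if (length(fg) == 0L) return(mask)
  tabs <- tabulate(fg)
  keep <- which.max(tabs)
  out <- binary_mask(mask$grid, array(lab == keep, dim = mask$grid$shape))
  attr(out, "discarded_fraction") <- 1 - tabs[keep] / length(fg)
  out
}

#' Triangulated surface of a binary mask
#'
#' Extracts the closed surface separating foreground from background, in mm
#' patient coordinates: the zero level set of the signed Euclidean distance
#' field (positive inside), triangulated by marching tetrahedra. Using the
#' signed distance rather than the raw 0/1 field places vertices with
#' sub-voxel accuracy and avoids the staircase area bias of a binary
#' isosurface; every foreground voxel centre has strictly positive signed
#' distance and therefore lies inside the closed surface. The volume is
#' padded with one background layer so surfaces touching the grid boundary
#' still close.
#'
#' The signed distance field is smoothed once with a 3x3x3 box filter to
#' remove lattice direction bias, then clamped so foreground voxel centres
#' stay strictly positive and background centres strictly negative — the
#' smoothing never moves the surface across a voxel centre.
#'
#' @param mask A nonempty [binary_mask()].
#' @return A [tube_mesh()] (watertight triangle mesh, no branch labels).
#' @export
surface_from_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) {
    abort("mask is empty.", class = "bronchoplan_input_error")
  }
  grid <- mask$grid
  d <- grid$shape + 2L
  padded <- array(FALSE, dim = d)
  padded[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- mask$data
  inside <- sqrt(cpp_edt_sq(as.vector(padded), d, grid$spacing))
  outside <- sqrt(cpp_edt_sq(as.vector(!padded), d, grid$spacing))
  field <- box_mean3(array(inside - outside, dim = d))
  eps <- 0.25 * min(grid$spacing)
  field[padded & field < eps] <- eps
  field[!padded & field > -eps] <- -eps
  res <- cpp_marching_tetra(as.vector(field), d, grid$spacing,
                            grid$origin - grid$spacing, 0)
  tube_mesh(res$vertices, res$faces)
}

# 3x3x3 box mean with edge renormalization
box_mean3 <- function(a) {
  d <- dim(a)
  out <- array(0, d)
  cnt <- array(0, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    si <- max(1, 1 - dx):min(d[1], d[1] - dx)
    sj <- max(1, 1 - dy):min(d[2], d[2] - dy)
    sk <- max(1, 1 - dz):min(d[3], d[3] - dz)
    out[si + dx, sj + dy, sk + dz] <- out[si + dx, sj + dy, sk + dz] + a[si, sj, sk]
    cnt[si + dx, sj + dy, sk + dz] <- cnt[si + dx, sj + dy, sk + dz] + 1
  }
  out / cnt
}

#' Dice overlap coefficient of two masks
#'
#' `2|A & B| / (|A| + |B|)` on matching grids.
#'
#' @param a,b [binary_mask()] objects with identical shapes.
#' @return Numeric scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"),
            identical(dim(a$data), dim(b$data)))
  denom <- sum(a$data) + sum(b$data)
  if (denom == 0) return(1)
  2 * sum(a$data & b$data) / denom
}
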
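#' Parameters of a bifurcating airway phantom
#'
#' Ground-truth phantoms are binary-splitting trees in LPS mm coordinates:
#' a trachea growing inferiorly (toward -z) that bifurcates `depth` times,
#' with branch length and radius scaled per generation. The defaults follow a
#' Weibel-like symmetric model: the radius ratio 0.79 is approximately
#' 2^(-1/3), the scaling under which total cross-sectional area grows
#' gently down the tree, and the trachea (9 mm radius, 100 mm length) is the
#' widest branch — radii decrease strictly with generation.
#'
#' @param depth Integer >= 0, generations beyond the trachea.
#' @param trachea_length Trachea length, mm.
#' @param trachea_radius Trachea radius, mm.
#' @param length_ratio Per-generation length scale, in (0, 1].
#' @param radius_ratio Per-generation radius scale, in (0, 1].
#' @param branching_angle Angle between each child and its parent direction,
#'   degrees.
#' @param points_per_branch Number of centerline positions stored per branch,
#'   >= 2.
#' @param angle_jitter Standard deviation (degrees) of random perturbations
#'   of the branching and azimuthal angles; 0 gives a perfectly regular tree.
#' @param seed Integer seed driving the jitter; generation is deterministic
#'   for a fixed seed.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(depth = 2L, trachea_length = 100, trachea_radius = 9,
                           length_ratio = 0.7, radius_ratio = 0.79,
                           branching_angle = 35, points_per_branch = 20L,
                           angle_jitter = 0, seed = 1L) {
  p <- list(depth = as.integer(depth), trachea_length = trachea_length,
            trachea_radius = trachea_radius, length_ratio = length_ratio,
            radius_ratio = radius_ratio, branching_angle = branching_angle,
            points_per_branch = as.integer(points_per_branch),
            angle_jitter = angle_jitter, seed = as.integer(seed))
  ok <- p$depth >= 0L && p$trachea_length > 0 && p$trachea_radius > 0 &&
    p$length_ratio > 0 && p$length_ratio <= 1 &&
    p$radius_ratio > 0 && p$radius_ratio <= 1 &&
    p$points_per_branch >= 2L && p$angle_jitter >= 0 &&
    is.finite(p$branching_angle)
  if (!isTRUE(ok)) {
    abort("invalid phantom parameters.", class = "bronchoplan_parameter_error")
  }
  structure(p, class = "phantom_params")
}

# Run code with a temporary RNG state seeded from `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rotate_vec <- function(v, axis, theta) {
  # Rodrigues rotation of v about unit axis by theta radians
  a <- axis / sqrt(sum(axis^2))
  v * cos(theta) + pracma_cross(a, v) * sin(theta) +
    a * sum(a * v) * (1 - cos(theta))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a ground-truth bifurcating airway tree
#'
#' Builds the phantom tree described by [phantom_params()]: a trachea at the
#' top (most superior point, largest z) growing toward -z, each non-terminal
#' branch splitting into two children rotated by ± the branching angle. The
#' bifurcation plane alternates (rotates 90 degrees) each generation so the
#' tree is genuinely three-dimensional and self-avoiding.
#'
#' @param params A [phantom_params()].
#' @return An [airway_tree()]; branch ids are assigned in breadth-first
#'   order with the trachea as id 1.
#' @export
generate_airway_tree <- function(params = phantom_params()) {
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  with_seed(params$seed, {
    branches <- list()
    next_id <- 1L
    # queue entries: start point, unit direction, unit bifurcation-plane
    # normal, generation, parent id
    queue <- list(list(start = c(0, 0, 0), dir = c(0, 0, -1),
                       normal = c(1, 0, 0), gen = 0L, parent = NA_integer_))
    while (length(queue)) {
      node <- queue[[1L]]
      queue <- queue[-1L]
      id <- next_id
      next_id <- next_id + 1L
      len <- params$trachea_length * params$length_ratio^node$gen
      rad <- params$trachea_radius * params$radius_ratio^node$gen
      # the trachea includes its start; children start one step beyond the
      # bifurcation so the junction point belongs to the parent branch only
      t <- if (node$gen == 0L) {
        seq(0, 1, length.out = params$points_per_branch)
      } else {
        seq_len(params$points_per_branch) / params$points_per_branch
      }
      pos <- outer(rep(1, length(t)), node$start) + outer(t * len, node$dir)
      branches[[id]] <- new_branch(id, pos, parent_id = node$parent,
                                   generation = node$gen, radius = rad)
      if (!is.na(node$parent)) {
        pid <- node$parent
        branches[[pid]]$child_ids <- c(branches[[pid]]$child_ids, id)
      }
      if (node$gen < params$depth) {
        tip <- node$start + len * node$dir
        for (sgn in c(-1, 1)) {
          th <- (params$branching_angle +
                   if (params$angle_jitter > 0) rnorm(1, 0, params$angle_jitter) else 0) *
            pi / 180
          az <- if (params$angle_jitter > 0) {
            rnorm(1, 0, params$angle_jitter) * pi / 180
          } else 0
          axis <- if (az != 0) rotate_vec(node$normal, node$dir, az) else node$normal
          cdir <- rotate_vec(node$dir, axis, sgn * th)
          cdir <- cdir / sqrt(sum(cdir^2))
          cnorm <- pracma_cross(cdir, axis)
          cnorm <- cnorm / sqrt(sum(cnorm^2))
          queue <- c(queue, list(list(start = tip, dir = cdir, normal = cnorm,
                                      gen = node$gen + 1L, parent = id)))
        }
      }
    }
    airway_tree(branches)
  })
}

#' Grid enclosing a tree with a margin
#'
#' Convenience constructor of a [volume_grid()] whose physical extent covers
#' all tree centerline points plus a margin wide enough for the thickest
#' branch wall.
#'
#' @param tree An [airway_tree()].
#' @param spacing Length-3 (or scalar) mm voxel spacing.
#' @param margin Extra mm on every side; default 1.5x the largest branch
#'   radius plus two voxels.
#' @return A [volume_grid()].
#' @export
grid_for_tree <- function(tree, spacing, margin = NULL) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  radii <- vapply(tree$branches, function(b) b$radius, numeric(1))
  if (is.null(margin)) margin <- 1.5 * max(radii, 0, na.rm = TRUE) + 2 * max(spacing)
  bb <- tree_bbox(tree)
  origin <- bb$min - margin
  shape <- ceiling((bb$max + margin - origin) / spacing) + 1
  volume_grid(shape, spacing, origin)
}

#' Voxelize an airway tree into a binary mask
#'
#' A voxel is foreground iff its centre lies within the branch radius of any
#' centerline segment (capsule model; single-point branches become spheres).
#'
#' @param tree An [airway_tree()].
#' @param grid A [volume_grid()] whose physical extent contains the tree.
#' @return A [binary_mask()].
#' @export
voxelize_tree <- function(tree, grid) {
  pts <- tidy(tree)
  if (nrow(pts) == 0L) {
    abort("tree has no centerline positions.", class = "bronchoplan_input_error")
  }
  idx <- world_to_index(grid, as.matrix(pts[, c("x", "y", "z")]))
  if (!all(in_grid(grid, idx))) {
    abort("tree centerline extends outside the grid extent.",
          class = "bronchoplan_geometry_error")
  }
  mask <- array(FALSE, dim = grid$shape)
  for (b in tree$branches) {
    r <- b$radius
    if (!is.finite(r) || r <= 0) {
      abort("all branches need a positive radius for voxelization.",
            class = "bronchoplan_parameter_error")
    }
    p <- b$positions
    segs <- if (nrow(p) == 1L) list(list(a = p[1L, ], b = p[1L, ])) else {
      lapply(seq_len(nrow(p) - 1L),
             function(s) list(a = p[s, ], b = p[s + 1L, ]))
    }
    for (sg in segs) {
      mask <- fill_capsule(mask, grid, sg$a, sg$b, r)
    }
  }
  binary_mask(grid, mask)
}

fill_capsule <- function(mask, grid, a, b, r) {
  lo <- pmax(world_to_index(grid, pmin(a, b) - r)[1L, ], 1)
  hi <- pmin(world_to_index(grid, pmax(a, b) + r)[1L, ], grid$shape)
  if (any(lo > hi)) return(mask)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  ctr <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  P <- index_to_world(grid, ctr)
  u <- b - a
  L2 <- sum(u^2)
  if (L2 == 0) {
    d2 <- rowSums(sweep(P, 2, a, "-")^2)
  } else {
    t <- pmin(pmax(as.vector(sweep(P, 2, a, "-") %*% u) / L2, 0), 1)
    proj <- outer(rep(1, nrow(P)), a) + outer(t, u)
    d2 <- rowSums((P - proj)^2)
  }
  hit <- ctr[d2 <= r^2, , drop = FALSE]
  if (nrow(hit)) {
    lin <- hit[, 1] + grid$shape[1] * ((hit[, 2] - 1) +
                                         grid$shape[2] * (hit[, 3] - 1))
    mask[lin] <- TRUE
  }
  mask
}

# 26-neighbourhood binary dilation by one voxel (array shifting)
dilate26 <- function(arr) {
  d <- dim(arr)
  out <- arr
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    src_i <- max(1, 1 - dx):min(d[1], d[1] - dx)
    src_j <- max(1, 1 - dy):min(d[2], d[2] - dy)
    src_k <- max(1, 1 - dz):min(d[3], d[3] - dz)
    out[src_i + dx, src_j + dy, src_k + dz] <-
      out[src_i + dx, src_j + dy, src_k + dz] | arr[src_i, src_j, src_k]
  }
  out
}

#' Simulate a pseudo-CT volume from an airway mask
#'
#' Assigns CT-like Hounsfield intensities to an airway lumen mask: air in the
#' lumen at -1000 HU, a one-voxel soft-tissue wall shell at 0 HU around it,
#' and lung parenchyma background at -800 HU, plus optional Gaussian noise.
#' The wall shell is every background voxel 26-adjacent to the lumen, so a
#' sub-air threshold region grown from inside the lumen cannot cross it.
#'
#' @param mask A [binary_mask()] of the airway lumen.
#' @param noise_sd Gaussian noise standard deviation, HU, >= 0.
#' @param seed Integer seed for the noise; the result is deterministic for a
#'   fixed seed.
#' @param lumen_hu,wall_hu,background_hu Mean intensities of the three
#'   compartments.
#' @return An [image_volume()].
#' @export
simulate_ct <- function(mask, noise_sd = 0, seed = 1L,
                        lumen_hu = -1000, wall_hu = 0, background_hu = -800) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.finite(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "bronchoplan_parameter_error")
  }
  lumen <- mask$data
  wall <- dilate26(lumen) & !lumen
  hu <- array(background_hu, dim = dim(lumen))
  hu[wall] <- wall_hu
  hu[lumen] <- lumen_hu
  if (noise_sd > 0) {
    hu <- hu + with_seed(seed, array(rnorm(length(hu), 0, noise_sd), dim = dim(hu)))
  }
  image_volume(mask$grid, hu)
}
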
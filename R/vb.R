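#' Smooth a centerline polyline
#'
#' Moving-average smoothing of an ordered polyline, the preprocessing step
#' for drawing virtual-bronchoscopy tubes and camera paths. The averaging
#' window is clamped symmetrically at the ends, so the first and last points
#' are always unchanged and the output has the same number of points.
#'
#' @param positions Ordered positions: a data frame with `x`, `y`, `z` or an
#'   Nx3 matrix, N >= 2.
#' @param window Odd integer window size >= 1; 1 is the identity.
#' @return Smoothed positions, same type and length as the input.
#' @export
smooth_centerline <- function(positions, window = 5L) {
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L || window %% 2L == 0L) {
    abort("`window` must be an odd integer >= 1.", class = "bronchoplan_parameter_error")
  }
  P <- rbind3(positions)
  n <- nrow(P)
  if (n < 2L) {
    abort("need at least 2 positions.", class = "bronchoplan_input_error")
  }
  h <- (window - 1L) %/% 2L
  out <- P
  if (h > 0L) {
    for (i in seq_len(n)) {
      hi <- min(h, i - 1L, n - i)
      if (hi > 0L) out[i, ] <- colMeans(P[(i - hi):(i + hi), , drop = FALSE])
    }
  }
  if (is.data.frame(positions)) {
    res <- positions
    res$x <- out[, 1]; res$y <- out[, 2]; res$z <- out[, 3]
    res
  } else {
    out
  }
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) abort("zero-length vector.", class = "bronchoplan_geometry_error")
  v / n
}

# rotate u by the rotation taking unit vector t0 to unit vector t1
transport_rotation <- function(u, t0, t1) {
  ax <- pracma_cross(t0, t1)
  s <- sqrt(sum(ax^2))
  co <- sum(t0 * t1)
  if (s < 1e-12) {
    if (co > 0) return(u)
    # 180-degree turn: rotate about any axis perpendicular to t0
    ax <- pracma_cross(t0, c(1, 0, 0))
    if (sum(ax^2) < 1e-12) ax <- pracma_cross(t0, c(0, 1, 0))
    return(rotate_vec(u, unit(ax), pi))
  }
  rotate_vec(u, ax / s, atan2(s, co))
}

# tangents of an ordered polyline: central differences, one-sided at the ends
polyline_tangents <- function(P) {
  n <- nrow(P)
  T <- matrix(0, n, 3)
  T[1, ] <- P[2, ] - P[1, ]
  T[n, ] <- P[n, ] - P[n - 1, ]
  if (n > 2L) T[2:(n - 1), ] <- P[3:n, , drop = FALSE] - P[1:(n - 2), , drop = FALSE]
  t(apply(T, 1, unit))
}

# initial up vector: patient anterior (0,-1,0 in LPS) projected orthogonal to
# the first tangent; falls back to superior if the tangent is anterior
initial_up <- function(t0) {
  for (cand in list(c(0, -1, 0), c(0, 0, 1), c(1, 0, 0))) {
    u <- cand - sum(cand * t0) * t0
    if (sum(u^2) > 1e-12) return(unit(u))
  }
  stop("unreachable")
}

#' Default generation-to-radius map for synthetic tubes
#'
#' Geometric decay `r(g) = trachea_radius * ratio^g`, so the trachea
#' (generation 0) is always the widest tube and radii shrink monotonically
#' down the tree.
#'
#' @param trachea_radius Tube radius at generation 0, mm.
#' @param ratio Per-generation decay in (0, 1).
#' @return A function `generation -> radius (mm)`.
#' @export
default_radius_fn <- function(trachea_radius = 9, ratio = 0.7) {
  force(trachea_radius); force(ratio)
  function(generation) trachea_radius * ratio^generation
}

#' Synthetic airway tube mesh
#'
#' Draws artificial tubes around the (smoothed) branch centerlines, one tube
#' per branch, with the tube radius set by the branch generation — the
#' trachea is the widest. Each branch tube is a closed triangulated surface:
#' `n_circ` circumferential vertices per ring swept with a
#' parallel-transport frame, capped with triangle fans at both ends, so each
#' per-branch tube is watertight.
#'
#' @param tree An [airway_tree()].
#' @param radius_fn Function mapping generation to tube radius (mm), positive.
#' @param n_circ Number of circumferential vertices per ring, >= 3.
#' @param window Smoothing window passed to [smooth_centerline()].
#' @return A [tube_mesh()] with `face_branch` labels and `branch_radius`.
#' @export
generate_tube_mesh <- function(tree, radius_fn = default_radius_fn(),
                               n_circ = 16L, window = 5L) {
  n_circ <- as.integer(n_circ)
  if (n_circ < 3L) {
    abort("`n_circ` must be >= 3.", class = "bronchoplan_parameter_error")
  }
  gens <- branch_generations(tree)
  verts <- list()
  faces <- list()
  fb <- list()
  nv <- 0L
  radii <- c()
  for (b in tree$branches) {
    g <- gens[[as.character(b$id)]]
    r <- radius_fn(g)
    if (!is.finite(r) || r <= 0) {
      abort("`radius_fn` must return positive radii.",
            class = "bronchoplan_parameter_error")
    }
    radii[as.character(b$id)] <- r
    P <- b$positions
    if (nrow(P) < 2L) next
    P <- smooth_centerline(P, window = min(window, largest_odd(nrow(P))))
    tube <- sweep_tube(P, r, n_circ)
    faces[[length(faces) + 1L]] <- tube$faces + nv
    verts[[length(verts) + 1L]] <- tube$vertices
    fb[[length(fb) + 1L]] <- rep(b$id, nrow(tube$faces))
    nv <- nv + nrow(tube$vertices)
  }
  tube_mesh(do.call(rbind, verts), do.call(rbind, faces),
            face_branch = unlist(fb), branch_radius = radii)
}

largest_odd <- function(n) if (n %% 2L == 0L) n - 1L else n

# closed tube: rings of n_circ vertices at every centerline point with a
# parallel-transport frame, plus fan caps at both ends
sweep_tube <- function(P, r, n_circ) {
  n <- nrow(P)
  tang <- polyline_tangents(P)
  u <- initial_up(tang[1, ])
  theta <- 2 * pi * (seq_len(n_circ) - 1) / n_circ
  verts <- matrix(0, n * n_circ + 2L, 3L)
  for (i in seq_len(n)) {
    if (i > 1L) {
      u <- transport_rotation(u, tang[i - 1, ], tang[i, ])
      u <- unit(u - sum(u * tang[i, ]) * tang[i, ])
    }
    w <- pracma_cross(tang[i, ], u)
    ring <- outer(rep(1, n_circ), P[i, ]) +
      r * (outer(cos(theta), u) + outer(sin(theta), w))
    verts[((i - 1L) * n_circ + 1L):(i * n_circ), ] <- ring
  }
  c_start <- n * n_circ + 1L
  c_end <- n * n_circ + 2L
  verts[c_start, ] <- P[1, ]
  verts[c_end, ] <- P[n, ]
  faces <- list()
  for (i in seq_len(n - 1L)) {
    a <- (i - 1L) * n_circ + seq_len(n_circ)
    b <- i * n_circ + seq_len(n_circ)
    a2 <- a[c(2:n_circ, 1L)]
    b2 <- b[c(2:n_circ, 1L)]
    faces[[length(faces) + 1L]] <- cbind(a, b, b2)
    faces[[length(faces) + 1L]] <- cbind(a, b2, a2)
  }
  ring1 <- seq_len(n_circ)
  ringN <- (n - 1L) * n_circ + seq_len(n_circ)
  faces[[length(faces) + 1L]] <- cbind(c_start, ring1[c(2:n_circ, 1L)], ring1)
  faces[[length(faces) + 1L]] <- cbind(c_end, ringN, ringN[c(2:n_circ, 1L)])
  list(vertices = verts, faces = do.call(rbind, faces))
}

#' Fly-through camera path along a route
#'
#' Samples camera poses along the smoothed route by arc length, every
#' `step_mm`, for the virtual-bronchoscopy fly-through: the camera position
#' is restricted to the (smoothed) centerline, the view direction is the
#' local forward tangent, and the up vector is carried along by parallel
#' transport from an anatomically meaningful start (patient anterior) and
#' then rolled about the view direction. The parameter `p` in `[0, 1]` maps
#' linearly to arc length, matching a position slider.
#'
#' @param route An `airway_route` from [route_to_target()], or a data frame
#'   of ordered `x`, `y`, `z` positions (>= 2 points).
#' @param step_mm Arc-length sampling step, mm, > 0.
#' @param roll Roll angle about the view direction, radians.
#' @param window Smoothing window applied to the route first.
#' @param reversed Traverse the route tip-to-trachea instead.
#' @return A `camera_path` tibble: `p`, `x`, `y`, `z`, `vx`, `vy`, `vz`
#'   (unit view direction), `ux`, `uy`, `uz` (unit up vector), `roll`.
#' @export
fly_through_path <- function(route, step_mm = 2, roll = 0, window = 5L,
                             reversed = FALSE) {
  P <- if (inherits(route, "airway_route")) {
    as.matrix(route$positions[, c("x", "y", "z")])
  } else {
    rbind3(route)
  }
  P <- P[!duplicated(P), , drop = FALSE]
  if (nrow(P) < 2L) {
    abort("route must have at least 2 distinct positions.",
          class = "bronchoplan_input_error")
  }
  if (!is.finite(step_mm) || step_mm <= 0) {
    abort("`step_mm` must be > 0.", class = "bronchoplan_parameter_error")
  }
  S <- smooth_centerline(P, window = min(window, largest_odd(nrow(P))))
  if (reversed) S <- S[rev(seq_len(nrow(S))), , drop = FALSE]
  seglen <- sqrt(rowSums((S[-1L, , drop = FALSE] - S[-nrow(S), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  L <- cum[length(cum)]
  s <- unique(c(seq(0, L, by = step_mm), L))
  # linear interpolation along the polyline keeps samples exactly on it
  pos <- cbind(stats::approx(cum, S[, 1], xout = s)$y,
               stats::approx(cum, S[, 2], xout = s)$y,
               stats::approx(cum, S[, 3], xout = s)$y)
  keep <- !duplicated(pos)
  pos <- pos[keep, , drop = FALSE]
  s <- s[keep]
  tang <- polyline_tangents(pos)
  n <- nrow(pos)
  up <- matrix(0, n, 3)
  u <- initial_up(tang[1, ])
  for (i in seq_len(n)) {
    if (i > 1L) {
      u <- transport_rotation(u, tang[i - 1, ], tang[i, ])
      u <- unit(u - sum(u * tang[i, ]) * tang[i, ])
    }
    up[i, ] <- if (roll != 0) rotate_vec(u, tang[i, ], roll) else u
  }
  out <- tibble::tibble(p = if (L > 0) s / L else 0,
                        x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        vx = tang[, 1], vy = tang[, 2], vz = tang[, 3],
                        ux = up[, 1], uy = up[, 2], uz = up[, 3],
                        roll = roll)
  class(out) <- c("camera_path", class(out))
  out
}

#' Axis-aligned cut planes at a centerline position
#'
#' The cut-planes VB mode slices the scene with three planes through the
#' current position on the centerline, aligned with the patient axes:
#' sagittal (normal along x), coronal (normal along y) and axial (normal
#' along z).
#'
#' @param position Length-3 finite mm position.
#' @return A `cut_plane_set`: list with `center` and `planes`, each plane a
#'   list of `point` and unit `normal`.
#' @export
cut_planes_at <- function(position) {
  position <- as.numeric(position)
  if (length(position) != 3L || any(!is.finite(position))) {
    abort("`position` must be 3 finite coordinates.",
          class = "bronchoplan_input_error")
  }
  planes <- list(
    sagittal = list(point = position, normal = c(1, 0, 0)),
    coronal  = list(point = position, normal = c(0, 1, 0)),
    axial    = list(point = position, normal = c(0, 0, 1))
  )
  structure(list(center = position, planes = planes), class = "cut_plane_set")
}

#' Overview camera seeing the whole airway tree
#'
#' Places the camera on a sphere around the tree's bounding-box centre, at a
#' radius of 1.5x the bounding-box diagonal, looking at the centre — an
#' angled, elevated view of the entire thorax. Elevation 0 / azimuth 0 puts
#' the camera on the anterior axis; positive elevation raises it superiorly
#' and positive azimuth swings it toward the patient's right.
#'
#' @param tree A nonempty [airway_tree()].
#' @param elevation Elevation angle, degrees.
#' @param azimuth Azimuth angle, degrees.
#' @param radius_scale Camera distance as a multiple of the bounding-box
#'   diagonal, >= 1.5.
#' @return A `camera_pose`: list with `position`, unit `view_dir`, unit
#'   `up` (orthogonal to `view_dir`), `roll`.
#' @export
overview_camera <- function(tree, elevation = 30, azimuth = 30,
                            radius_scale = 1.5) {
  if (n_branches(tree) == 0L) {
    abort("empty tree.", class = "bronchoplan_input_error")
  }
  bb <- tree_bbox(tree)
  ctr <- (bb$min + bb$max) / 2
  diag_len <- sqrt(sum((bb$max - bb$min)^2))
  if (diag_len == 0) diag_len <- 1
  R <- max(radius_scale, 1.5) * diag_len
  el <- elevation * pi / 180
  az <- azimuth * pi / 180
  # LPS: anterior = -y, superior = +z, patient right = -x
  dir <- c(-sin(az) * cos(el), -cos(az) * cos(el), sin(el))
  pos <- ctr + R * dir
  view <- unit(ctr - pos)
  up <- c(0, 0, 1) - sum(c(0, 0, 1) * view) * view
  if (sum(up^2) < 1e-12) up <- c(0, -1, 0) - sum(c(0, -1, 0) * view) * view
  camera_pose(pos, view, unit(up))
}

#' Camera pose
#'
#' @param position Length-3 mm position.
#' @param view_dir Unit view direction.
#' @param up Unit up vector, orthogonal to `view_dir`.
#' @param roll Roll angle, radians.
#' @return A `camera_pose` object; unit-length and orthogonality are
#'   enforced to within 1e-9 / 1e-6.
#' @export
camera_pose <- function(position, view_dir, up, roll = 0) {
  if (abs(sqrt(sum(view_dir^2)) - 1) > 1e-9 || abs(sqrt(sum(up^2)) - 1) > 1e-9) {
    abort("`view_dir` and `up` must be unit vectors.",
          class = "bronchoplan_parameter_error")
  }
  if (abs(sum(view_dir * up)) > 1e-6) {
    abort("`up` must be orthogonal to `view_dir`.",
          class = "bronchoplan_parameter_error")
  }
  structure(list(position = as.numeric(position), view_dir = as.numeric(view_dir),
                 up = as.numeric(up), roll = roll),
            class = "camera_pose")
}
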
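helix <- function(n = 200, r = 10, pitch = 2, turns = 3) {
  t <- seq(0, turns * 2 * pi, length.out = n)
  cbind(r * cos(t), r * sin(t), pitch * t)
}

test_that("smoothing with window 1 is the identity and keeps endpoints fixed", {
  P <- helix(50)
  expect_identical(smooth_centerline(P, 1), P)
  S <- smooth_centerline(P, 7)
  expect_identical(nrow(S), nrow(P))
  expect_equal(S[1, ], P[1, ])
  expect_equal(S[nrow(S), ], P[nrow(P), ])
  expect_error(smooth_centerline(P, 4), class = "bronchoplan_parameter_error")
  expect_error(smooth_centerline(P[1, , drop = FALSE], 3),
               class = "bronchoplan_input_error")
})

test_that("collinear polylines are fixed points of smoothing", {
  P <- cbind(seq(0, 10, length.out = 21), seq(0, -5, length.out = 21),
             seq(2, 30, length.out = 21))
  for (w in c(3, 5, 9)) {
    expect_equal(smooth_centerline(P, w), P)
  }
})

test_that("smoothing a zig-zag strictly shortens it, and never lengthens twice", {
  set.seed(3)
  zig <- cbind(seq_len(40), rep(c(0, 2), 20), rnorm(40, sd = 0.5))
  len <- function(P) sum(sqrt(rowSums(diff(P)^2)))
  s1 <- smooth_centerline(zig, 3)
  expect_lt(len(s1), len(zig))
  s2 <- smooth_centerline(s1, 3)
  expect_lte(len(s2), len(s1))
})

test_that("a straight tube has the analytic lateral area and sphere topology", {
  L <- 100
  r <- 5
  n_circ <- 16
  tr <- airway_tree(list(new_branch(1L, cbind(0, 0, seq(0, L, length.out = 21)),
                                    radius = r)))
  m <- generate_tube_mesh(tr, radius_fn = function(g) r, n_circ = n_circ)
  expect_true(mesh_is_watertight(m))
  expect_identical(mesh_euler_characteristic(m), 2L)
  lateral <- mesh_area(m) - 2 * ngon_area(r, n_circ)
  expect_lt(abs(lateral - 2 * pi * r * L) / (2 * pi * r * L), 0.05)
})

test_that("tube radii follow the generation map with the trachea largest", {
  tr <- generate_airway_tree(phantom_params(depth = 2))
  m <- generate_tube_mesh(tr)
  rad <- m$branch_radius
  troot <- rad[[as.character(tr$root_id)]]
  for (id in names(tr$branches)) {
    if (as.integer(id) != tr$root_id) expect_lt(rad[[id]], troot)
  }
  # every branch sub-mesh is watertight on its own
  for (id in c("1", "4")) {
    expect_true(mesh_is_watertight(mesh_branch(m, as.integer(id))))
  }
  # ring vertices sit at the tube radius from the smoothed centerline
  b <- tr$branches[["4"]]
  S <- smooth_centerline(b$positions, 5)
  sub <- mesh_branch(m, 4L)
  ring_v <- sub$vertices[unique(as.vector(sub$faces)), ]
  dists <- apply(ring_v, 1, dist_to_polyline, S = S)
  interior <- dists > 1e-9  # cap centres lie on the line itself
  expect_lt(max(abs(dists[interior] - rad[["4"]])), rad[["4"]] * 0.35)
  expect_error(generate_tube_mesh(tr, n_circ = 2),
               class = "bronchoplan_parameter_error")
  expect_error(generate_tube_mesh(tr, radius_fn = function(g) -1),
               class = "bronchoplan_parameter_error")
})

test_that("a straight route gives constant tangents along +y", {
  P <- cbind(0, seq(0, 50, by = 1), 0)
  cam <- fly_through_path(P, step_mm = 2)
  expect_true(all(abs(cam$vx) < 1e-12))
  expect_true(all(abs(cam$vy - 1) < 1e-12))
  expect_true(all(abs(cam$vz) < 1e-12))
  # p runs linearly in arc length from 0 to 1
  expect_equal(cam$p[1], 0)
  expect_equal(cam$p[nrow(cam)], 1)
  expect_true(all(diff(cam$p) > 0))
})

test_that("tangents agree with an independent finite-difference oracle", {
  P <- helix(400)
  cam <- fly_through_path(P, step_mm = 1, window = 1)
  pos <- as.matrix(cam[, c("x", "y", "z")])
  n <- nrow(pos)
  fd <- matrix(0, n, 3)
  fd[1, ] <- pos[2, ] - pos[1, ]
  fd[n, ] <- pos[n, ] - pos[n - 1, ]
  fd[2:(n - 1), ] <- pos[3:n, ] - pos[1:(n - 2), ]
  fd <- fd / sqrt(rowSums(fd^2))
  expect_lt(max(abs(as.matrix(cam[, c("vx", "vy", "vz")]) - fd)), 1e-6)
})

test_that("camera poses stay on the smoothed route with stable up vectors", {
  tr <- generate_airway_tree(phantom_params(depth = 2, angle_jitter = 3, seed = 2))
  td <- tidy(tr)
  tgt <- as.numeric(td[nrow(td), c("x", "y", "z")]) + c(3, -2, -4)
  rt <- route_to_target(tr, tgt)
  cam <- fly_through_path(rt, step_mm = 2)
  S <- smooth_centerline(
    as.matrix(rt$positions[, c("x", "y", "z")]), 5)
  offs <- apply(as.matrix(cam[, c("x", "y", "z")]), 1, dist_to_polyline, S = S)
  expect_lt(max(offs), 1e-6)
  V <- as.matrix(cam[, c("vx", "vy", "vz")])
  U <- as.matrix(cam[, c("ux", "uy", "uz")])
  expect_lt(max(abs(rowSums(V^2) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(U^2) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(U * V))), 1e-6)
  steps <- acos(pmin(1, rowSums(U[-1, ] * U[-nrow(U), ]))) * 180 / pi
  expect_lt(max(steps), 10)
})

test_that("roll rotates the up vector with period 2*pi", {
  P <- helix(100)
  c0 <- fly_through_path(P, step_mm = 2, roll = 0)
  c2 <- fly_through_path(P, step_mm = 2, roll = 2 * pi)
  expect_equal(as.matrix(c0[, c("ux", "uy", "uz")]),
               as.matrix(c2[, c("ux", "uy", "uz")]))
  cr <- fly_through_path(P, step_mm = 2, roll = pi / 2)
  expect_gt(max(abs(as.matrix(c0[, c("ux", "uy", "uz")]) -
                      as.matrix(cr[, c("ux", "uy", "uz")]))), 0.5)
  # a reversed traversal starts where the forward one ends
  cb <- fly_through_path(P, step_mm = 2, reversed = TRUE)
  expect_equal(as.numeric(cb[1, c("x", "y", "z")]),
               as.numeric(c0[nrow(c0), c("x", "y", "z")]))
  expect_error(fly_through_path(P[1, , drop = FALSE]),
               class = "bronchoplan_input_error")
  expect_error(fly_through_path(P, step_mm = 0),
               class = "bronchoplan_parameter_error")
})

test_that("cut planes pass through their centre with axis-aligned normals", {
  p <- c(12.5, -30.2, 44.9)
  cp <- cut_planes_at(p)
  expect_equal(cp$center, p)
  normals <- t(vapply(cp$planes, function(pl) pl$normal, numeric(3)))
  expect_equal(unname(normals), diag(3))
  for (pl in cp$planes) {
    expect_equal(sum((p - pl$point) * pl$normal), 0)
  }
  # sagittal normal is the patient x axis
  expect_equal(cp$planes$sagittal$normal, c(1, 0, 0))
  # moving only in z leaves sagittal and coronal planes unchanged
  cp2 <- cut_planes_at(p + c(0, 0, 10))
  expect_equal(cp$planes$sagittal$point[1], cp2$planes$sagittal$point[1])
  expect_equal(cp$planes$coronal$point[2], cp2$planes$coronal$point[2])
  expect_false(isTRUE(all.equal(cp$planes$axial$point[3],
                                cp2$planes$axial$point[3])))
  expect_error(cut_planes_at(c(1, NA, 3)), class = "bronchoplan_input_error")
})

test_that("the overview camera sees the whole tree inside a 60-degree cone", {
  tr <- generate_airway_tree(phantom_params(depth = 3))
  cam <- overview_camera(tr)
  expect_equal(sum(cam$view_dir^2), 1)
  expect_lt(abs(sum(cam$view_dir * cam$up)), 1e-6)
  P <- as.matrix(tidy(tr)[, c("x", "y", "z")])
  rel <- sweep(P, 2, cam$position, "-")
  ang <- acos(rel %*% cam$view_dir / sqrt(rowSums(rel^2)))
  expect_lt(max(ang) * 180 / pi, 30)  # well inside a 60-degree cone
  # elevation 0 / azimuth 0 puts the camera on the anterior axis
  cam0 <- overview_camera(tr, elevation = 0, azimuth = 0)
  bb_ctr <- (apply(P, 2, min) + apply(P, 2, max)) / 2
  d <- unname(cam0$position - bb_ctr)
  expect_equal(d[1], 0)
  expect_equal(d[3], 0)
  expect_lt(d[2], 0)  # anterior is -y in LPS
})

test_that("plane clipping splits a cylinder tube at the right area", {
  L <- 80
  r <- 4
  n_circ <- 24
  tr <- airway_tree(list(new_branch(1L, cbind(0, 0, seq(0, L, length.out = 41)),
                                    radius = r)))
  m <- generate_tube_mesh(tr, radius_fn = function(g) r, n_circ = n_circ)
  full <- mesh_area(m)
  cap <- ngon_area(r, n_circ)
  # no-op when the plane is fully below
  below <- clip_mesh_by_plane(m, c(0, 0, -50), c(0, 0, 1))
  expect_equal(mesh_area(below), full)
  expect_identical(nrow(below$faces), nrow(m$faces))
  # full clip when fully above
  above <- clip_mesh_by_plane(m, c(0, 0, 500), c(0, 0, 1))
  expect_identical(nrow(above$faces), 0L)
  # half clip: lateral area halves, nothing survives below the plane
  half <- clip_mesh_by_plane(m, c(0, 0, L / 2), c(0, 0, 1))
  lat_half <- mesh_area(half) - cap
  expect_lt(abs(lat_half - (full - 2 * cap) / 2) / ((full - 2 * cap) / 2), 0.05)
  expect_gte(min(half$vertices[unique(as.vector(half$faces)), 3]), L / 2 - 1e-9)
})
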
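test_that("phantom tree has the full binary-tree structure for each depth", {
  for (d in 0:6) {
    tr <- generate_airway_tree(phantom_params(depth = d, points_per_branch = 3))
    g <- glance(tr)
    expect_identical(g$n_branches, as.integer(2^(d + 1) - 1))
    expect_identical(g$n_terminal, as.integer(2^d))
    expect_identical(g$max_generation, d)
  }
  # base case: a single parentless trachea at generation 0
  tr0 <- generate_airway_tree(phantom_params(depth = 0))
  expect_length(tr0$branches, 1L)
  expect_true(is.na(tr0$branches[[1]]$parent_id))
  expect_identical(tr0$branches[[1]]$generation, 0L)
})

test_that("phantom generation is deterministic for a fixed seed", {
  a <- generate_airway_tree(phantom_params(depth = 3, angle_jitter = 5, seed = 7))
  b <- generate_airway_tree(phantom_params(depth = 3, angle_jitter = 5, seed = 7))
  c <- generate_airway_tree(phantom_params(depth = 3, angle_jitter = 5, seed = 8))
  expect_identical(tidy(a), tidy(b))
  expect_false(identical(tidy(a), tidy(c)))
})

test_that("radii strictly decrease with generation when radius_ratio < 1", {
  tr <- generate_airway_tree(phantom_params(depth = 4))
  td <- dplyr::distinct(tidy(tr), branch_id, generation, radius)
  by_gen <- dplyr::summarise(dplyr::group_by(td, generation),
                             r = max(radius), .groups = "drop")
  expect_true(all(diff(by_gen$r) < 0))
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_params(depth = -1), class = "bronchoplan_parameter_error")
  expect_error(phantom_params(trachea_radius = 0), class = "bronchoplan_parameter_error")
  expect_error(phantom_params(length_ratio = 1.2), class = "bronchoplan_parameter_error")
  expect_error(phantom_params(points_per_branch = 1), class = "bronchoplan_parameter_error")
})

test_that("voxelizing a single point yields a sphere of the right volume", {
  r <- 6
  sp <- 0.75  # spacing well below r
  tr <- airway_tree(list(new_branch(1L, matrix(c(0, 0, 0), 1), radius = r)))
  g <- volume_grid(rep(ceiling(2 * r / sp) + 7, 3), rep(sp, 3),
                   rep(-r - 3 * sp, 3))
  m <- voxelize_tree(tr, g)
  vol <- sum(m$data) * prod(g$spacing)
  expect_lt(abs(vol - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.1)
})

test_that("every centerline point's voxel is foreground after voxelization", {
  tr <- generate_airway_tree(phantom_params(depth = 2))
  g <- grid_for_tree(tr, 1.5)
  m <- voxelize_tree(tr, g)
  idx <- world_to_index(g, as.matrix(tidy(tr)[, c("x", "y", "z")]))
  expect_true(all(m$data[idx]))
})

test_that("voxelization rejects degenerate or out-of-grid trees", {
  tr <- generate_airway_tree(phantom_params(depth = 1))
  tiny <- volume_grid(c(5, 5, 5), c(1, 1, 1), c(0, 0, 0))
  expect_error(voxelize_tree(tr, tiny), class = "bronchoplan_geometry_error")
  empty <- airway_tree(list(new_branch(1L, matrix(numeric(), 0, 3))))
  expect_error(voxelize_tree(empty, tiny), class = "bronchoplan_input_error")
})

test_that("noiseless pseudo-CT has exactly the three compartment values", {
  tr <- generate_airway_tree(phantom_params(depth = 1))
  m <- voxelize_tree(tr, grid_for_tree(tr, 2.5))
  ct <- simulate_ct(m, noise_sd = 0)
  expect_setequal(unique(as.vector(ct$data)), c(-1000, -800, 0))
  expect_true(all(ct$data[m$data] == -1000))
})

test_that("lumen mean intensity matches -1000 HU within sampling error", {
  tr <- generate_airway_tree(phantom_params(depth = 1))
  m <- voxelize_tree(tr, grid_for_tree(tr, 2.5))
  sd <- 30
  ct <- simulate_ct(m, noise_sd = sd, seed = 11)
  lum <- ct$data[m$data]
  expect_lt(abs(mean(lum) + 1000), 3 * sd / sqrt(length(lum)))
})

test_that("pseudo-CT is deterministic per seed and rejects negative noise", {
  tr <- generate_airway_tree(phantom_params(depth = 1))
  m <- voxelize_tree(tr, grid_for_tree(tr, 2.5))
  a <- simulate_ct(m, noise_sd = 20, seed = 3)
  b <- simulate_ct(m, noise_sd = 20, seed = 3)
  expect_identical(a$data, b$data)
  expect_error(simulate_ct(m, noise_sd = -1), class = "bronchoplan_parameter_error")
})

test_that("wall shell separates lumen from parenchyma in every direction", {
  # a sub-air threshold region grown inside the lumen must not be able to
  # take a 26-step into background without crossing the 0 HU wall
  tr <- generate_airway_tree(phantom_params(depth = 1))
  m <- voxelize_tree(tr, grid_for_tree(tr, 2.5))
  ct <- simulate_ct(m, noise_sd = 0)
  d <- dim(m$data)
  lum <- which(m$data, arr.ind = TRUE)
  for (off in list(c(1, 1, 1), c(-1, 1, 0), c(0, -1, -1))) {
    nb <- sweep(lum, 2, off, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    vals <- ct$data[nb[ok, , drop = FALSE]]
    expect_true(all(vals %in% c(-1000, 0)))
  }
})
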
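test_that("pinpoint CRUD obeys conflict and lookup semantics", {
  s <- new_session(withr::local_tempdir())
  before <- s$targets
  s <- pinpoint(s, "add", "lesion", c(1, 2, 3))
  expect_error(pinpoint(s, "add", "lesion", c(0, 0, 0)),
               class = "bronchoplan_conflict_error")
  s <- pinpoint(s, "add", "node", c(4, 5, 6), color = "#00FF00")
  s <- pinpoint(s, "rename", "node", new_name = "lymph")
  expect_error(pinpoint(s, "rename", "lymph", new_name = "lesion"),
               class = "bronchoplan_conflict_error")
  expect_error(pinpoint(s, "move", "ghost", c(0, 0, 0)),
               class = "bronchoplan_lookup_error")
  s <- pinpoint(s, "move", "lesion", c(9, 9, 9))
  expect_equal(as.numeric(s$targets[s$targets$name == "lesion",
                                    c("x", "y", "z")]),
               c(9, 9, 9))
  s <- pinpoint(s, "recolor", "lesion", color = "#0000FF")
  expect_identical(s$targets$color[s$targets$name == "lesion"], "#0000FF")
  # add then delete restores the original target set
  s <- pinpoint(s, "delete", "lymph")
  s <- pinpoint(s, "delete", "lesion")
  expect_identical(s$targets[, c("name", "x", "y", "z")],
                   before[, c("name", "x", "y", "z")])
})

test_that("moving a target changes the route computed afterwards", {
  tr <- generate_airway_tree(phantom_params(depth = 2))
  s <- new_session(withr::local_tempdir())
  s$trees$main <- tr
  s <- pinpoint(s, "add", "lesion", c(40, 10, -150))
  r1 <- route_to_target(s$trees$main, s$targets[s$targets$name == "lesion", ])
  s <- pinpoint(s, "move", "lesion", c(-40, -10, -150))
  r2 <- route_to_target(s$trees$main, s$targets[s$targets$name == "lesion", ])
  expect_false(identical(r1$positions, r2$positions))
})

test_that("session save -> load -> save produces identical files", {
  cfg <- bronchoplan_config(phantom_depth = 1, voxel_spacing = 2.5)
  ph <- generate_phantom_data(withr::local_tempdir(), config = cfg)
  d1 <- withr::local_tempdir()
  s <- new_session(d1)
  s <- pinpoint(s, "add", "lesion", c(10, 20, -30))
  s$volumes$ct <- ph$ct
  s$masks$lumen <- ph$mask
  s$trees$phantom <- ph$tree
  s$routes$main <- route_to_target(ph$tree, c(10, 20, -30))
  save_session(s)
  s2 <- load_session(d1)
  d2 <- withr::local_tempdir()
  s2$patient_dir <- d2
  save_session(s2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  expect_equal(s2$trees$phantom$branches, ph$tree$branches, tolerance = 1e-12)
})

test_that("full workflow writes every stage artifact for a phantom CT", {
  cfg <- bronchoplan_config(phantom_depth = 2, voxel_spacing = 2)
  ph <- generate_phantom_data(withr::local_tempdir(), config = cfg)
  seedpt <- trachea_top(ph$tree) + c(0, 0, -4)
  td <- tidy(ph$tree)
  tip <- as.numeric(td[nrow(td), c("x", "y", "z")]) + c(4, -3, -5)
  out <- withr::local_tempdir()
  res <- run_workflow(ph$paths$ct_mhd, seedpt, tip, out_dir = out,
                      config = cfg, log = NULL)
  expect_identical(res$status, "complete")
  expected <- c("mask.mhd", "centerline.csv", "surface.stl", "tree.json",
                "targets.json", "route.json", "route.csv", "tubes.stl",
                "camera_path.json", "camera_path.csv", "cut_planes.json",
                "workflow.log")
  expect_true(all(file.exists(file.path(out, expected))))
  # reconstructed tree topology matches the ground truth
  expect_identical(tree_topology_signature(res$tree),
                   tree_topology_signature(ph$tree))
  # route artifacts reload consistently
  rt <- read_route_json(file.path(out, "route.json"))
  expect_equal(rt$positions, res$route$positions, tolerance = 1e-12)
})

test_that("a missing target stops the pipeline after extract as pending", {
  cfg <- bronchoplan_config(phantom_depth = 1, voxel_spacing = 2.5)
  ph <- generate_phantom_data(withr::local_tempdir(), config = cfg)
  out <- withr::local_tempdir()
  res <- run_workflow(ph$paths$ct_mhd, trachea_top(ph$tree) + c(0, 0, -4),
                      NULL, out_dir = out, config = cfg, log = NULL)
  expect_identical(res$status, "pinpoint pending")
  expect_true(file.exists(file.path(out, "tree.json")))
  expect_false(file.exists(file.path(out, "route.json")))
})

test_that("reruns with the same seed produce byte-identical JSON artifacts", {
  cfg <- bronchoplan_config(phantom_depth = 1, voxel_spacing = 2.5, seed = 5L)
  ph <- generate_phantom_data(withr::local_tempdir(), config = cfg)
  seedpt <- trachea_top(ph$tree) + c(0, 0, -4)
  td <- tidy(ph$tree)
  tip <- as.numeric(td[nrow(td), c("x", "y", "z")])
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  run_workflow(ph$paths$ct_mhd, seedpt, tip, out_dir = out1, config = cfg,
               log = NULL)
  run_workflow(ph$paths$ct_mhd, seedpt, tip, out_dir = out2, config = cfg,
               log = NULL)
  for (f in c("tree.json", "route.json", "camera_path.json", "targets.json",
              "cut_planes.json")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("a failing stage reports its name and keeps earlier artifacts", {
  cfg <- bronchoplan_config(phantom_depth = 1, voxel_spacing = 2.5)
  ph <- generate_phantom_data(withr::local_tempdir(), config = cfg)
  out <- withr::local_tempdir()
  # seed outside the volume: the segment stage must fail loudly
  expect_error(
    run_workflow(ph$paths$ct_mhd, ph$ct$grid$origin - 100, NULL,
                 out_dir = out, config = cfg, log = NULL),
    class = "bronchoplan_stage_error")
  expect_true(file.exists(file.path(out, "workflow.log")))
})

test_that("the settings directory is created once with factory defaults", {
  d <- file.path(withr::local_tempdir(), "settings")
  p <- settings_dir(d)
  expect_true(file.exists(file.path(p, "config.json")))
  cfg <- load_settings(p)
  expect_equal(cfg$threshold, bronchoplan_config()$threshold)
  # deleting the folder resets to factory state on next use
  unlink(p, recursive = TRUE)
  p2 <- settings_dir(d)
  expect_true(file.exists(file.path(p2, "config.json")))
})
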
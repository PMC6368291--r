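#' Run the full planning pipeline
#'
#' Executes the workflow stages in order — import, extract (segmentation +
#' centerline + surface + tree), pinpoint, route, virtual-bronchoscopy
#' geometry — writing each stage's artifact to `out_dir` and logging each
#' stage with its parameters and timing. Stages whose inputs are satisfied
#' run automatically; if no target is given the pipeline stops after the
#' extract stage and reports the pinpoint stage as pending. Artifacts
#' contain no timestamps, so a rerun with the same inputs and config is
#' byte-identical.
#'
#' @param ct Path to a CT volume (DICOM folder, `.mhd`, `.nii`/`.nii.gz`) or
#'   an [image_volume()].
#' @param seed_point Length-3 mm seed inside the trachea lumen.
#' @param target_point Length-3 mm target position, or `NULL` to stop after
#'   extraction.
#' @param out_dir Output directory for artifacts.
#' @param config A [bronchoplan_config()].
#' @param target_name Name recorded for the target.
#' @param log Logging function taking a single string (e.g. `message`);
#'   `NULL` silences logging. A copy of the log is written to
#'   `workflow.log` in `out_dir`.
#' @return Invisibly, a list with the computed objects (`volume`, `mask`,
#'   `centerline`, `surface`, `tree`, `route`, `tubes`, `camera_path`,
#'   `cut_planes`), the artifact `paths`, and `status` (`"complete"` or
#'   `"pinpoint pending"`).
#' @export
run_workflow <- function(ct, seed_point, target_point = NULL,
                         out_dir = ".", config = bronchoplan_config(),
                         target_name = "target", log = message) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character()
  stamp <- function(stage, detail) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%OS2"), stage, detail)
    log_lines <<- c(log_lines, line)
    if (!is.null(log)) log(line)
  }
  run_stage <- function(stage, detail, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stamp(stage, paste("FAILED:", conditionMessage(e)))
      writeLines(log_lines, file.path(out_dir, "workflow.log"))
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
            class = "bronchoplan_stage_error", parent = e)
    })
    stamp(stage, sprintf("%s (%.2f s)", detail, proc.time()[["elapsed"]] - t0))
    res
  }
  paths <- list()
  art <- function(name) {
    paths[[name]] <<- file.path(out_dir, name)
    paths[[name]]
  }

  vol <- run_stage("import", "volume loaded", {
    if (inherits(ct, "image_volume")) ct else read_volume(ct)
  })

  mask <- run_stage("extract/segment",
                    sprintf("threshold %g HU, guard %g", config$threshold,
                            config$max_fraction), {
    segment_airways(vol, seed_point, threshold = config$threshold,
                    max_fraction = config$max_fraction,
                    step_hu = config$step_hu)
  })
  write_volume_mhd(mask, art("mask.mhd"))

  centerline <- run_stage("extract/centerline", "skeletonized", {
    extract_centerline(mask)
  })
  write_centerline_csv(centerline, art("centerline.csv"))

  surface <- run_stage("extract/surface", "isosurface", {
    surface_from_mask(mask)
  })
  write_stl(surface, art("surface.stl"))

  tree <- run_stage("extract/tree", "branch model built", {
    cr <- config$connectivity_radius
    build_tree(centerline,
               connectivity_radius = if (is.null(cr) || is.na(cr)) NULL else cr,
               prune_below = config$prune_below)
  })
  write_tree_json(tree, art("tree.json"))

  if (is.null(target_point)) {
    stamp("pinpoint", "pending (no target given); stopping after extract")
    writeLines(log_lines, file.path(out_dir, "workflow.log"))
    return(invisible(list(volume = vol, mask = mask, centerline = centerline,
                          surface = surface, tree = tree, paths = paths,
                          status = "pinpoint pending")))
  }

  tgt <- run_stage("pinpoint", target_name, {
    target(target_name, target_point, created = "")
  })
  write_targets_json(tgt, art("targets.json"))

  route <- run_stage("route", "route-to-target", {
    route_to_target(tree, tgt)
  })
  write_route_json(route, art("route.json"))
  write_route_csv(route, art("route.csv"))

  tubes <- run_stage("vb/tubes", sprintf("%d circumferential vertices",
                                         config$n_circ), {
    generate_tube_mesh(tree,
                       radius_fn = default_radius_fn(config$tube_trachea_radius,
                                                     config$tube_radius_ratio),
                       n_circ = config$n_circ, window = config$smooth_window)
  })
  write_stl(tubes, art("tubes.stl"))

  cam <- run_stage("vb/fly_through", sprintf("step %g mm", config$step_mm), {
    fly_through_path(route, step_mm = config$step_mm, roll = config$roll,
                     window = config$smooth_window)
  })
  write_camera_path_json(cam, art("camera_path.json"))
  write_camera_path_csv(cam, art("camera_path.csv"))

  planes <- run_stage("vb/cut_planes", "at route end", {
    cut_planes_at(as.numeric(tail(as.matrix(route$positions[, c("x", "y", "z")]),
                                  1)))
  })
  write_cut_planes_json(planes, art("cut_planes.json"))

  writeLines(log_lines, file.path(out_dir, "workflow.log"))
  invisible(list(volume = vol, mask = mask, centerline = centerline,
                 surface = surface, tree = tree, route = route, tubes = tubes,
                 camera_path = cam, cut_planes = planes, paths = paths,
                 status = "complete"))
}

#' Generate phantom artifacts on disk
#'
#' Builds the ground-truth phantom for a configuration and writes the tree
#' (JSON), lumen mask (MetaImage and NIfTI) and pseudo-CT (MetaImage and
#' NIfTI) to a directory — the standard way to produce a self-contained
#' test data set for the pipeline.
#'
#' @param out_dir Output directory.
#' @param config A [bronchoplan_config()].
#' @return Invisibly, a list with `tree`, `mask`, `ct` and the written
#'   `paths`.
#' @export
generate_phantom_data <- function(out_dir = ".", config = bronchoplan_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  params <- phantom_params(depth = config$phantom_depth,
                           trachea_length = config$trachea_length,
                           trachea_radius = config$trachea_radius,
                           length_ratio = config$length_ratio,
                           radius_ratio = config$radius_ratio,
                           branching_angle = config$branching_angle,
                           points_per_branch = config$points_per_branch,
                           angle_jitter = config$angle_jitter,
                           seed = config$seed)
  tree <- generate_airway_tree(params)
  grid <- grid_for_tree(tree, config$voxel_spacing)
  mask <- voxelize_tree(tree, grid)
  ct <- simulate_ct(mask, noise_sd = config$noise_sd, seed = config$seed)
  paths <- list(
    tree = file.path(out_dir, "phantom_tree.json"),
    mask_mhd = file.path(out_dir, "phantom_mask.mhd"),
    ct_mhd = file.path(out_dir, "phantom_ct.mhd"),
    mask_nii = file.path(out_dir, "phantom_mask.nii.gz"),
    ct_nii = file.path(out_dir, "phantom_ct.nii.gz")
  )
  write_tree_json(tree, paths$tree)
  write_volume_mhd(mask, paths$mask_mhd)
  write_volume_mhd(ct, paths$ct_mhd)
  write_volume_nifti(mask, paths$mask_nii)
  write_volume_nifti(ct, paths$ct_nii)
  invisible(list(tree = tree, mask = mask, ct = ct, paths = paths))
}
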
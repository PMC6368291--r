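#' Pipeline configuration
#'
#' All tunable parameters of the planning pipeline with their defaults, as
#' one named list. Unknown keys are rejected. All randomness in the pipeline
#' (phantom jitter, CT noise) flows from the single `seed`.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A `bronchoplan_config` list.
#'
#' @section Parameters:
#' * `seed` (1): master RNG seed.
#' * `phantom_depth` (2), `trachea_length` (100 mm), `trachea_radius`
#'   (9 mm), `length_ratio` (0.7), `radius_ratio` (0.79), `branching_angle`
#'   (35 deg), `points_per_branch` (20), `angle_jitter` (0 deg): phantom
#'   generator, see [phantom_params()].
#' * `voxel_spacing` (1.5 mm): phantom voxelization spacing.
#' * `noise_sd` (30 HU): pseudo-CT noise.
#' * `threshold` (-500 HU), `max_fraction` (0.25), `step_hu` (50):
#'   region growing, see [segment_airways()].
#' * `connectivity_radius` (NA = auto), `prune_below` (3): tree building,
#'   see [build_tree()].
#' * `smooth_window` (5): centerline smoothing window.
#' * `tube_trachea_radius` (9 mm), `tube_radius_ratio` (0.7), `n_circ`
#'   (16): synthetic tubes, see [generate_tube_mesh()].
#' * `step_mm` (2 mm), `roll` (0 rad): fly-through sampling.
#' @export
bronchoplan_config <- function(...) {
  defaults <- list(
    seed = 1L,
    phantom_depth = 2L, trachea_length = 100, trachea_radius = 9,
    length_ratio = 0.7, radius_ratio = 0.79, branching_angle = 35,
    points_per_branch = 20L, angle_jitter = 0,
    voxel_spacing = 1.5, noise_sd = 30,
    threshold = -500, max_fraction = 0.25, step_hu = 50,
    connectivity_radius = NA_real_, prune_below = 3L,
    smooth_window = 5L,
    tube_trachea_radius = 9, tube_radius_ratio = 0.7, n_circ = 16L,
    step_mm = 2, roll = 0
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")),
          class = "bronchoplan_parameter_error")
  }
  # NULLs (e.g. a JSON null for an NA default) fall back to the default
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  structure(modifyList(defaults, overrides), class = "bronchoplan_config")
}

#' Settings directory
#'
#' Created on first use with the default configuration written to
#' `config.json`; deleting the directory resets the defaults to factory
#' state. The location can be overridden with the `bronchoplan.settings`
#' option or the `BRONCHOPLAN_SETTINGS` environment variable.
#'
#' @param path Settings directory path.
#' @return The directory path.
#' @export
settings_dir <- function(path = getOption(
    "bronchoplan.settings",
    Sys.getenv("BRONCHOPLAN_SETTINGS",
               file.path(path.expand("~"), ".bronchoplan_settings")))) {
  if (!dir.exists(path)) {
    dir.create(path, recursive = TRUE)
    write_config(bronchoplan_config(), file.path(path, "config.json"))
  }
  path
}

#' @rdname settings_dir
#' @export
load_settings <- function(path = settings_dir()) {
  read_config(file.path(path, "config.json"))
}

#' Read a configuration file
#'
#' YAML or JSON (by extension) with keys from [bronchoplan_config()];
#' unknown keys are rejected.
#'
#' @param path File path.
#' @return A `bronchoplan_config`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  bronchoplan_config(vals)
}

#' @rdname read_config
#' @param config A `bronchoplan_config`.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}
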
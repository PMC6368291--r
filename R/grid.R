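#' Regular voxel grid in patient coordinates
#'
#' A `volume_grid` describes a regular 3D lattice in LPS (left-posterior-
#' superior) patient coordinates, the DICOM convention, in millimetres.
#' The centre of voxel `(i, j, k)` (1-based R indices) lies at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param shape Integer vector of length 3, voxel counts per axis.
#' @param spacing Numeric vector of length 3, mm per voxel, all > 0.
#' @param origin Numeric vector of length 3, mm, centre of the first voxel.
#' @return A `volume_grid` object.
#' @export
volume_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(shape < 1L)) {
    abort("`shape` must be 3 positive integers.", class = "bronchoplan_parameter_error")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive numbers (mm).", class = "bronchoplan_parameter_error")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort("`origin` must be 3 finite numbers (mm).", class = "bronchoplan_parameter_error")
  }
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

#' Convert between voxel indices and patient coordinates
#'
#' @param grid A [volume_grid()].
#' @param index Nx3 matrix (or length-3 vector) of 1-based voxel indices.
#' @param xyz Nx3 matrix (or length-3 vector) of mm positions.
#' @return `index_to_world()` returns an Nx3 matrix of mm positions at voxel
#'   centres; `world_to_index()` returns an Nx3 integer matrix of the nearest
#'   voxel indices (not clamped to the grid).
#' @export
index_to_world <- function(grid, index) {
  index <- rbind3(index)
  sweep(sweep(index - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' @rdname index_to_world
#' @export
world_to_index <- function(grid, xyz) {
  xyz <- rbind3(xyz)
  idx <- sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
  storage.mode(idx) <- "double"
  round(idx)
}

in_grid <- function(grid, index) {
  index <- rbind3(index)
  apply(index >= 1, 1, all) & apply(sweep(index, 2, grid$shape, "<="), 1, all)
}

rbind3 <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  x
}

#' Scalar image volume on a grid
#'
#' @param grid A [volume_grid()].
#' @param data 3D numeric array of intensities (HU for CT-like data) whose
#'   dimensions equal `grid$shape`.
#' @return An `image_volume` object.
#' @export
image_volume <- function(grid, data) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!identical(dim(data), as.integer(grid$shape))) {
    abort("`data` dimensions must equal `grid$shape`.", class = "bronchoplan_parameter_error")
  }
  structure(list(grid = grid, data = data), class = "image_volume")
}

#' Binary mask on a grid
#'
#' @param grid A [volume_grid()].
#' @param data 3D array coercible to logical, dimensions equal to `grid$shape`.
#' @return A `binary_mask` object; `data` is stored as a logical array.
#' @export
binary_mask <- function(grid, data) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!identical(dim(data), as.integer(grid$shape))) {
    abort("`data` dimensions must equal `grid$shape`.", class = "bronchoplan_parameter_error")
  }
  d <- array(as.logical(data), dim = dim(data))
  if (anyNA(d)) abort("mask values must be 0/1.", class = "bronchoplan_parameter_error")
  structure(list(grid = grid, data = d), class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(x$grid$shape, collapse = " x "),
      " voxels, range [", signif(min(x$data), 5), ", ", signif(max(x$data), 5),
      "]\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(x$grid$shape, collapse = " x "),
      " voxels, ", sum(x$data), " foreground\n", sep = "")
  invisible(x)
}
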
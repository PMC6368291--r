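#' Read and write centerline point sets as CSV
#'
#' Plain CSV with header `x,y,z,radius` (radius optional on read), LPS mm.
#'
#' @param points A data frame with `x`, `y`, `z` and optionally `radius`.
#' @param path File path.
#' @return `write_centerline_csv()` returns `path` invisibly;
#'   `read_centerline_csv()` returns a tibble.
#' @export
write_centerline_csv <- function(points, path) {
  cols <- intersect(c("x", "y", "z", "radius"), names(points))
  readr::write_csv(as.data.frame(points)[, cols], path)
  invisible(path)
}

#' @rdname write_centerline_csv
#' @export
read_centerline_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read and write polylines as VTK XML PolyData (.vtp)
#'
#' ASCII VTP with one polyline cell connecting the points in order, readable
#' by ParaView and other VTK-based viewers.
#'
#' @param points Ordered positions: data frame with `x`, `y`, `z` or Nx3
#'   matrix.
#' @param path File path.
#' @return `write_vtp_polyline()` returns `path` invisibly;
#'   `read_vtp_polyline()` returns a tibble of positions in polyline order.
#' @export
write_vtp_polyline <- function(points, path) {
  P <- rbind3(points)
  n <- nrow(P)
  coords <- paste(apply(P, 1, function(r) paste(format(r, digits = 17), collapse = " ")),
                  collapse = " ")
  doc <- paste0(
    "<?xml version=\"1.0\"?>\n",
    "<VTKFile type=\"PolyData\" version=\"0.1\" byte_order=\"LittleEndian\">\n",
    "  <PolyData>\n",
    "    <Piece NumberOfPoints=\"", n, "\" NumberOfVerts=\"0\" NumberOfLines=\"1\"",
    " NumberOfStrips=\"0\" NumberOfPolys=\"0\">\n",
    "      <Points>\n",
    "        <DataArray type=\"Float64\" NumberOfComponents=\"3\" format=\"ascii\">",
    coords, "</DataArray>\n",
    "      </Points>\n",
    "      <Lines>\n",
    "        <DataArray type=\"Int64\" Name=\"connectivity\" format=\"ascii\">",
    paste(0:(n - 1), collapse = " "), "</DataArray>\n",
    "        <DataArray type=\"Int64\" Name=\"offsets\" format=\"ascii\">", n,
    "</DataArray>\n",
    "      </Lines>\n",
    "    </Piece>\n",
    "  </PolyData>\n",
    "</VTKFile>\n")
  writeLines(doc, path, sep = "")
  invisible(path)
}

#' @rdname write_vtp_polyline
#' @export
read_vtp_polyline <- function(path) {
  doc <- xml2::read_xml(path)
  pts_node <- xml2::xml_find_first(doc, ".//Points/DataArray")
  vals <- as.numeric(strsplit(trimws(xml2::xml_text(pts_node)), "\\s+")[[1]])
  P <- matrix(vals, ncol = 3, byrow = TRUE)
  conn_node <- xml2::xml_find_first(doc, ".//Lines/DataArray[@Name='connectivity']")
  if (!inherits(conn_node, "xml_missing")) {
    conn <- as.integer(strsplit(trimws(xml2::xml_text(conn_node)), "\\s+")[[1]]) + 1L
    P <- P[conn, , drop = FALSE]
  }
  tibble::tibble(x = P[, 1], y = P[, 2], z = P[, 3])
}

#' Write a mesh as ASCII STL
#'
#' @param mesh A [tube_mesh()].
#' @param path File path.
#' @param name Solid name written into the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "bronchoplan") {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  if (nrow(f)) {
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    cc <- v[f[, 3], , drop = FALSE]
    u <- b - a
    w <- cc - a
    n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
    nl <- sqrt(rowSums(n^2))
    nl[nl == 0] <- 1
    n <- n / nl
    fmt <- function(m) apply(m, 1, function(r) paste(format(r, digits = 9), collapse = " "))
    block <- paste0("facet normal ", fmt(n), "\n",
                    "  outer loop\n",
                    "    vertex ", fmt(a), "\n",
                    "    vertex ", fmt(b), "\n",
                    "    vertex ", fmt(cc), "\n",
                    "  endloop\n",
                    "endfacet")
    writeLines(block, con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Read an ASCII STL file
#'
#' Vertices are de-duplicated exactly so watertight meshes read back as
#' watertight.
#'
#' @param path File path.
#' @return A [tube_mesh()].
#' @export
read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  nums <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  key <- apply(nums, 1, paste, collapse = "|")
  uk <- !duplicated(key)
  ids <- match(key, key[uk])
  verts <- nums[uk, , drop = FALSE]
  faces <- matrix(ids, ncol = 3, byrow = TRUE)
  tube_mesh(verts, faces)
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh A [tube_mesh()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  if (nrow(v)) {
    writeLines(apply(v, 1, function(r) paste(format(r, digits = 17), collapse = " ")), con)
  }
  if (nrow(f)) {
    writeLines(apply(f - 1L, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  }
  invisible(path)
}

#' Serialize an airway tree to JSON
#'
#' Schema: `root_id` plus one record per branch with `id`, `parent_id`
#' (null for the trachea), `generation`, `radius` and an Nx3 `positions`
#' list in mm. The same schema is used for ground-truth phantom trees and
#' trees built from centerlines.
#'
#' @param tree An [airway_tree()].
#' @param path File path.
#' @return `write_tree_json()` returns `path` invisibly;
#'   `read_tree_json()` returns an [airway_tree()].
#' @export
write_tree_json <- function(tree, path) {
  branches <- lapply(tree$branches, function(b) {
    list(id = b$id,
         parent_id = if (is.na(b$parent_id)) NULL else b$parent_id,
         child_ids = b$child_ids,
         generation = b$generation,
         radius = if (is.na(b$radius)) NULL else b$radius,
         positions = unname(apply(b$positions, 1, as.numeric, simplify = FALSE)))
  })
  jsonlite::write_json(list(root_id = tree$root_id, branches = unname(branches)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path)
  branches <- lapply(obj$branches, function(b) {
    pos <- do.call(rbind, lapply(b$positions, as.numeric))
    pid <- unlist(b$parent_id)
    rad <- unlist(b$radius)
    new_branch(b$id, pos,
               parent_id = if (length(pid)) as.integer(pid) else NA_integer_,
               child_ids = as.integer(unlist(b$child_ids) %||% integer()),
               generation = b$generation,
               radius = if (length(rad)) as.numeric(rad) else NA_real_)
  })
  airway_tree(branches)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a route to JSON or CSV
#'
#' JSON carries the ordered positions with branch ids, the target, the gap
#' to the target and the route metrics; CSV carries the positions table.
#'
#' @param route An `airway_route`.
#' @param path File path.
#' @return The path, invisibly (writers); `read_route_json()` returns an
#'   `airway_route`.
#' @export
write_route_json <- function(route, path) {
  tgt <- route$target
  obj <- list(
    target = list(name = tgt$name[1], position = c(tgt$x[1], tgt$y[1], tgt$z[1]),
                  color = tgt$color[1]),
    gap_mm = route$gap_mm,
    metrics = as.list(route_metrics(route)),
    branch_ids = route$positions$branch_id,
    generations = route$positions$generation,
    positions = unname(apply(as.matrix(route$positions[, c("x", "y", "z")]), 1,
                             as.numeric, simplify = FALSE))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_route_json
#' @export
read_route_json <- function(path) {
  obj <- jsonlite::read_json(path)
  P <- do.call(rbind, lapply(obj$positions, as.numeric))
  pos <- tibble::tibble(x = P[, 1], y = P[, 2], z = P[, 3],
                        branch_id = unlist(obj$branch_ids),
                        generation = unlist(obj$generations))
  tgt <- target(obj$target$name, as.numeric(unlist(obj$target$position)),
                color = obj$target$color, created = NA)
  structure(list(positions = pos, target = tgt, gap_mm = obj$gap_mm),
            class = "airway_route")
}

#' @rdname write_route_json
#' @export
write_route_csv <- function(route, path) {
  readr::write_csv(route$positions, path)
  invisible(path)
}

#' Serialize targets to JSON
#'
#' @param targets A tibble of targets (rows from [target()]).
#' @param path File path.
#' @return The path invisibly; `read_targets_json()` returns the tibble.
#' @export
write_targets_json <- function(targets, path) {
  recs <- lapply(seq_len(nrow(targets)), function(i) {
    list(name = targets$name[i],
         position = c(targets$x[i], targets$y[i], targets$z[i]),
         color = targets$color[i],
         created = as.character(targets$created[i]))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_targets_json
#' @export
read_targets_json <- function(path) {
  recs <- jsonlite::read_json(path)
  dplyr::bind_rows(lapply(recs, function(r) {
    target(r$name, as.numeric(unlist(r$position)), color = r$color,
           created = r$created %||% NA_character_)
  }))
}

#' Serialize a camera path to JSON or CSV
#'
#' @param poses A `camera_path` tibble from [fly_through_path()].
#' @param path File path.
#' @return The path, invisibly; `read_camera_path_json()` returns the tibble.
#' @export
write_camera_path_json <- function(poses, path) {
  recs <- lapply(seq_len(nrow(poses)), function(i) {
    list(p = poses$p[i],
         position = c(poses$x[i], poses$y[i], poses$z[i]),
         view_dir = c(poses$vx[i], poses$vy[i], poses$vz[i]),
         up = c(poses$ux[i], poses$uy[i], poses$uz[i]),
         roll = poses$roll[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_camera_path_json
#' @export
read_camera_path_json <- function(path) {
  recs <- jsonlite::read_json(path)
  out <- dplyr::bind_rows(lapply(recs, function(r) {
    tibble::tibble(p = r$p,
                   x = r$position[[1]], y = r$position[[2]], z = r$position[[3]],
                   vx = r$view_dir[[1]], vy = r$view_dir[[2]], vz = r$view_dir[[3]],
                   ux = r$up[[1]], uy = r$up[[2]], uz = r$up[[3]],
                   roll = r$roll)
  }))
  class(out) <- c("camera_path", class(out))
  out
}

#' @rdname write_camera_path_json
#' @export
write_camera_path_csv <- function(poses, path) {
  readr::write_csv(poses, path)
  invisible(path)
}

#' Serialize a cut-plane set to JSON
#'
#' @param planes A `cut_plane_set` from [cut_planes_at()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cut_planes_json <- function(planes, path) {
  obj <- list(center = planes$center,
              planes = lapply(planes$planes, function(p) {
                list(point = p$point, normal = p$normal)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
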
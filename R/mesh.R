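#' Triangle mesh container
#'
#' Triangulated surfaces (synthetic airway tubes, isosurfaces) in mm patient
#' coordinates. Faces optionally carry the id of the branch they belong to,
#' and the mesh can record the per-branch tube radius.
#'
#' @param vertices Nx3 numeric matrix, mm.
#' @param faces Mx3 integer matrix of 1-based vertex indices.
#' @param face_branch Optional integer vector (length M) of branch ids.
#' @param branch_radius Optional named numeric vector, mm per branch id.
#' @return A `tube_mesh` object.
#' @export
tube_mesh <- function(vertices, faces, face_branch = NULL, branch_radius = NULL) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || (nrow(faces) > 0L && ncol(faces) != 3L)) {
    abort("vertices and faces must have 3 columns.", class = "bronchoplan_parameter_error")
  }
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    abort("face indices out of range.", class = "bronchoplan_parameter_error")
  }
  colnames(vertices) <- c("x", "y", "z")
  structure(list(vertices = vertices, faces = faces,
                 face_branch = face_branch, branch_radius = branch_radius),
            class = "tube_mesh")
}

#' @export
print.tube_mesh <- function(x, ...) {
  cat("<tube_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces", sep = "")
  if (!is.null(x$face_branch)) {
    cat(", ", length(unique(x$face_branch)), " branches", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Total surface area of a mesh
#'
#' @param mesh A [tube_mesh()].
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(0)
  v <- mesh$vertices
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  cc <- v[mesh$faces[, 3], , drop = FALSE]
  u <- b - a
  w <- cc - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  sum(sqrt(rowSums(n^2))) / 2
}

mesh_edge_table <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Is a mesh watertight?
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces.
#'
#' @param mesh A [tube_mesh()].
#' @return Logical scalar.
#' @export
mesh_is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  all(mesh_edge_table(mesh$faces) == 2L)
}

#' Euler characteristic V - E + F of a mesh
#'
#' Counts only vertices actually referenced by faces. A closed surface of
#' sphere topology has characteristic 2.
#'
#' @param mesh A [tube_mesh()].
#' @return Integer.
#' @export
mesh_euler_characteristic <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(0L)
  v <- length(unique(as.vector(mesh$faces)))
  e <- length(mesh_edge_table(mesh$faces))
  v - e + nrow(mesh$faces)
}

#' Extract the sub-mesh of a single branch
#'
#' @param mesh A [tube_mesh()] with `face_branch` labels.
#' @param branch_id Integer branch id.
#' @return A [tube_mesh()] of that branch only.
#' @export
mesh_branch <- function(mesh, branch_id) {
  if (is.null(mesh$face_branch)) {
    abort("mesh has no branch labels.", class = "bronchoplan_input_error")
  }
  keep <- mesh$face_branch == branch_id
  tube_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE],
            face_branch = mesh$face_branch[keep],
            branch_radius = mesh$branch_radius)
}

#' Clip a mesh by a plane
#'
#' Keeps the part of the mesh on the positive side of the plane (where
#' `(v - point) . normal >= 0`); triangles crossing the plane are split at
#' the plane. An empty result is allowed.
#'
#' @param mesh A [tube_mesh()].
#' @param point Length-3 mm point on the plane.
#' @param normal Length-3 plane normal (need not be unit length).
#' @return A [tube_mesh()].
#' @export
clip_mesh_by_plane <- function(mesh, point, normal) {
  n <- normal / sqrt(sum(normal^2))
  sd_all <- as.vector(sweep(mesh$vertices, 2, point, "-") %*% n)
  eps <- 1e-9
  verts <- lapply(seq_len(nrow(mesh$vertices)), function(i) mesh$vertices[i, ])
  out_faces <- list()
  out_branch <- integer()
  add_face <- function(a, b, c, br) {
    out_faces[[length(out_faces) + 1L]] <<- c(a, b, c)
    out_branch[[length(out_branch) + 1L]] <<- br
  }
  cut_cache <- new.env(parent = emptyenv())
  cut_point <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- get0(key, envir = cut_cache)
    if (!is.null(hit)) return(hit)
    t <- sd_all[i] / (sd_all[i] - sd_all[j])
    verts[[length(verts) + 1L]] <<- verts[[i]] + t * (verts[[j]] - verts[[i]])
    id <- length(verts)
    assign(key, id, envir = cut_cache)
    id
  }
  for (f in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[f, ]
    br <- if (is.null(mesh$face_branch)) NA_integer_ else mesh$face_branch[f]
    s <- sd_all[tri]
    inside <- s >= -eps
    if (all(inside)) {
      add_face(tri[1], tri[2], tri[3], br)
    } else if (any(inside)) {
      # Sutherland-Hodgman clip of the triangle against the half-space
      poly <- integer()
      for (e in 1:3) {
        i <- tri[e]
        j <- tri[if (e == 3) 1 else e + 1]
        if (sd_all[i] >= -eps) poly <- c(poly, i)
        if ((sd_all[i] > eps && sd_all[j] < -eps) ||
            (sd_all[i] < -eps && sd_all[j] > eps)) {
          poly <- c(poly, cut_point(i, j))
        }
      }
      if (length(poly) >= 3L) {
        for (e in 2:(length(poly) - 1L)) {
          add_face(poly[1], poly[e], poly[e + 1], br)
        }
      }
    }
  }
  V <- if (length(verts)) do.call(rbind, verts) else matrix(numeric(), 0, 3)
  F <- if (length(out_faces)) do.call(rbind, out_faces) else matrix(integer(), 0, 3)
  fb <- if (is.null(mesh$face_branch)) NULL else out_branch
  tube_mesh(V, F, face_branch = fb, branch_radius = mesh$branch_radius)
}
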
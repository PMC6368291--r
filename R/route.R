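#' Create a target (pinpointed point of interest)
#'
#' A named, colored point in LPS mm patient coordinates, typically a
#' suspicious lesion to be reached by bronchoscopy.
#'
#' @param name Nonempty name, unique within a session.
#' @param position Length-3 mm position.
#' @param color Color string (any R color or hex).
#' @param created Creation timestamp.
#' @return A one-row tibble with columns `name`, `x`, `y`, `z`, `color`,
#'   `created`.
#' @export
target <- function(name, position, color = "#FF0000", created = Sys.time()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("target `name` must be a nonempty string.", class = "bronchoplan_parameter_error")
  }
  position <- as.numeric(position)
  if (length(position) != 3L || any(!is.finite(position))) {
    abort("target `position` must be 3 finite mm coordinates.",
          class = "bronchoplan_parameter_error")
  }
  tibble::tibble(name = name, x = position[1], y = position[2],
                 z = position[3], color = color, created = created)
}

target_position <- function(tgt) {
  if (is.data.frame(tgt)) c(tgt$x[1], tgt$y[1], tgt$z[1]) else as.numeric(tgt)
}

#' Centerline position closest to a target
#'
#' Scans every stored position of every branch and returns the one at
#' minimal Euclidean distance from the target. Ties are broken by the
#' smallest branch id, then the smallest position index.
#'
#' @param tree An [airway_tree()].
#' @param tgt A [target()] (or a length-3 mm position).
#' @return A list with `branch_id`, `index` (position index within the
#'   branch), `position` (mm) and `distance` (mm).
#' @export
closest_centerline_point <- function(tree, tgt) {
  if (n_branches(tree) == 0L) {
    abort("empty tree.", class = "bronchoplan_input_error")
  }
  p <- target_position(tgt)
  best <- NULL
  ids <- sort(vapply(tree$branches, function(b) b$id, integer(1)))
  for (id in ids) {
    b <- tree$branches[[as.character(id)]]
    d <- sqrt(rowSums(sweep(b$positions, 2, p, "-")^2))
    i <- which.min(d)  # smallest index on ties
    if (is.null(best) || d[i] < best$distance) {
      best <- list(branch_id = b$id, index = i,
                   position = b$positions[i, ], distance = d[i])
    }
  }
  best
}

#' Route to target along the airway centerline
#'
#' The route-to-target algorithm: the centerline position closest to the
#' target is selected; all positions from it to the top (proximal end) of
#' its branch are included, then all positions of the parent branch, and so
#' on until the top of the trachea is reached; the collected path is then
#' reversed, so the route runs from the trachea top down to the point inside
#' the bronchi closest to the target. The route never leaves the airway:
#' the remaining distance from its last point to the target is reported as
#' `gap_mm`.
#'
#' @param tree An [airway_tree()].
#' @param tgt A [target()] (or a length-3 mm position).
#' @return An `airway_route`: list with `positions` (a tibble of `x`, `y`,
#'   `z`, `branch_id`, `generation`), `target`, and `gap_mm`.
#' @export
route_to_target <- function(tree, tgt) {
  cl <- closest_centerline_point(tree, tgt)
  gens <- branch_generations(tree)
  segs <- list()
  b <- tree$branches[[as.character(cl$branch_id)]]
  take <- seq_len(cl$index)
  repeat {
    segs[[length(segs) + 1L]] <-
      tibble::tibble(x = b$positions[take, 1], y = b$positions[take, 2],
                     z = b$positions[take, 3], branch_id = b$id,
                     generation = unname(gens[[as.character(b$id)]]))
    if (is.na(b$parent_id)) break
    b <- tree$branches[[as.character(b$parent_id)]]
    take <- seq_len(nrow(b$positions))
  }
  # segs run from the closest branch up to the root, each proximal-to-distal;
  # reversing the branch order yields the trachea-top-first route
  pos <- dplyr::bind_rows(rev(segs))
  if (!is.data.frame(tgt)) tgt <- target("target", target_position(tgt))
  structure(list(positions = pos, target = tgt, gap_mm = cl$distance,
                 closest = cl),
            class = "airway_route")
}

#' @export
print.airway_route <- function(x, ...) {
  m <- glance(x)
  cat("<airway_route> ", nrow(x$positions), " positions over ",
      m$n_branches, " branches, ", round(m$length_mm, 1),
      " mm, gap to target ", round(x$gap_mm, 2), " mm\n", sep = "")
  invisible(x)
}

#' Route positions as a tibble
#'
#' @param x An `airway_route`.
#' @param ... Unused.
#' @return A tibble with `x`, `y`, `z`, `branch_id`, `generation`, ordered
#'   from the trachea top to the point closest to the target.
#' @export
tidy.airway_route <- function(x, ...) x$positions

#' Summary metrics of a route
#'
#' @param x An `airway_route`.
#' @param ... Unused.
#' @return A one-row tibble: `length_mm` (polyline length), `n_branches`
#'   (distinct branches traversed), `max_generation`, `gap_mm` (distance
#'   from route end to the target).
#' @export
glance.airway_route <- function(x, ...) {
  route_metrics(x)
}

#' @rdname glance.airway_route
#' @param route An `airway_route`.
#' @export
route_metrics <- function(route) {
  p <- as.matrix(route$positions[, c("x", "y", "z")])
  tibble::tibble(
    length_mm = polyline_length(p),
    n_branches = length(unique(route$positions$branch_id)),
    max_generation = max(route$positions$generation),
    gap_mm = route$gap_mm
  )
}
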
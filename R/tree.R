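#' Airway branch tree
#'
#' The branch model of the airway tree. Each branch holds the ordered
#' centerline positions along it (first row proximal, i.e. nearest the
#' trachea; last row distal), a representative radius, its generation
#' (trachea = 0) and the parent/child branches it is connected to. Every
#' branch except the trachea has exactly one parent.
#'
#' @param branches List of branches created with [new_branch()].
#' @return An `airway_tree`: a list with `branches` (named by id) and
#'   `root_id`.
#' @seealso [build_tree()], [validate_tree()], [generate_airway_tree()]
#' @export
airway_tree <- function(branches) {
  ids <- vapply(branches, function(b) b$id, integer(1))
  if (anyDuplicated(ids)) {
    abort("branch ids must be unique.", class = "bronchoplan_input_error")
  }
  names(branches) <- as.character(ids)
  roots <- ids[vapply(branches, function(b) is.na(b$parent_id), logical(1))]
  if (length(roots) != 1L) {
    abort(sprintf("tree must have exactly one parentless branch (found %d).",
                  length(roots)),
          class = "bronchoplan_input_error")
  }
  structure(list(branches = branches, root_id = roots[[1L]]),
            class = "airway_tree")
}

#' @param id Integer branch id.
#' @param positions Nx3 numeric matrix of mm positions, proximal first.
#' @param parent_id Integer id of the parent branch, or `NA` for the trachea.
#' @param child_ids Integer vector of child branch ids.
#' @param generation Integer generation (trachea = 0).
#' @param radius Representative branch radius in mm (may be `NA`).
#' @rdname airway_tree
#' @export
new_branch <- function(id, positions, parent_id = NA_integer_,
                       child_ids = integer(), generation = 0L, radius = NA_real_) {
  positions <- rbind3(positions)
  storage.mode(positions) <- "double"
  colnames(positions) <- c("x", "y", "z")
  list(id = as.integer(id), parent_id = as.integer(parent_id),
       child_ids = as.integer(child_ids), generation = as.integer(generation),
       radius = as.numeric(radius), positions = positions)
}

#' @export
print.airway_tree <- function(x, ...) {
  g <- glance(x)
  cat("<airway_tree> ", g$n_branches, " branches (", g$n_terminal,
      " terminal), max generation ", g$max_generation, ", ",
      round(g$total_length_mm, 1), " mm of centerline\n", sep = "")
  invisible(x)
}

n_branches <- function(tree) length(tree$branches)

#' Terminal (leaf) branch ids of an airway tree
#'
#' @param tree An [airway_tree()].
#' @return Integer vector of ids of branches without children.
#' @export
terminal_branches <- function(tree) {
  ids <- vapply(tree$branches, function(b) b$id, integer(1))
  unname(ids[vapply(tree$branches, function(b) length(b$child_ids) == 0L,
                    logical(1))])
}

#' All centerline positions of a tree as a tibble
#'
#' One row per stored centerline position, in branch order and proximal-to-
#' distal order within each branch.
#'
#' @param x An [airway_tree()].
#' @param ... Unused.
#' @return A tibble with columns `branch_id`, `point`, `x`, `y`, `z`,
#'   `generation`, `radius`.
#' @export
tidy.airway_tree <- function(x, ...) {
  purrr::map_dfr(x$branches, function(b) {
    tibble::tibble(branch_id = b$id,
                   point = seq_len(nrow(b$positions)),
                   x = b$positions[, 1], y = b$positions[, 2],
                   z = b$positions[, 3],
                   generation = b$generation, radius = b$radius)
  })
}

#' One-row summary of an airway tree
#'
#' @param x An [airway_tree()].
#' @param ... Unused.
#' @return A tibble with branch counts, maximum generation and total
#'   centerline length.
#' @export
glance.airway_tree <- function(x, ...) {
  lens <- vapply(x$branches, function(b) polyline_length(b$positions), numeric(1))
  tibble::tibble(
    n_branches = n_branches(x),
    n_terminal = length(terminal_branches(x)),
    max_generation = max(vapply(x$branches, function(b) b$generation, integer(1))),
    total_length_mm = sum(lens)
  )
}

polyline_length <- function(p) {
  p <- rbind3(p)
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

tree_bbox <- function(tree) {
  pts <- as.matrix(tidy(tree)[, c("x", "y", "z")])
  list(min = apply(pts, 2, min), max = apply(pts, 2, max))
}

#' Position of the trachea top
#'
#' The most proximal (superior) point of the root branch — the entry point of
#' every route and fly-through.
#'
#' @param tree An [airway_tree()].
#' @return Length-3 mm position.
#' @export
trachea_top <- function(tree) {
  tree$branches[[as.character(tree$root_id)]]$positions[1L, ]
}

#' Generation of every branch
#'
#' The trachea is generation 0 and each child is its parent's generation
#' plus one; generations are recomputed here by breadth-first traversal from
#' the root rather than read from the stored branches.
#'
#' @param tree An [airway_tree()].
#' @return Named integer vector, `names` are branch ids.
#' @export
branch_generations <- function(tree) {
  gen <- setNames(rep(NA_integer_, n_branches(tree)), names(tree$branches))
  queue <- as.character(tree$root_id)
  gen[queue] <- 0L
  while (length(queue)) {
    id <- queue[[1L]]
    queue <- queue[-1L]
    kids <- as.character(tree$branches[[id]]$child_ids)
    gen[kids] <- gen[[id]] + 1L
    queue <- c(queue, kids)
  }
  gen
}

#' Check the structural invariants of an airway tree
#'
#' Reports, per invariant, whether the structure is a valid branch model:
#' a single parentless root, mutually consistent parent/child links, no
#' cycles, generations increasing by one along every parent link, and each
#' non-root branch starting near its parent.
#'
#' @param tree An object shaped like an [airway_tree()] (possibly invalid —
#'   this function never errors on malformed trees, it reports).
#' @param connectivity_radius Distance (mm) within which a child's proximal
#'   endpoint must lie of some parent position; `Inf` skips the check.
#' @return A tibble with columns `check`, `pass`, `detail`.
#' @export
validate_tree <- function(tree, connectivity_radius = Inf) {
  branches <- tree$branches
  ids <- vapply(branches, function(b) b$id, integer(1))
  by_id <- setNames(branches, as.character(ids))
  res <- list()
  note <- function(check, pass, detail = "") {
    res[[length(res) + 1L]] <<- tibble::tibble(check = check, pass = pass,
                                               detail = detail)
  }

  roots <- ids[vapply(branches, function(b) is.na(b$parent_id), logical(1))]
  note("single_root", length(roots) == 1L,
       paste0("parentless branches: ", paste(roots, collapse = ", ")))

  missing_parent <- ids[vapply(branches, function(b) {
    !is.na(b$parent_id) && !as.character(b$parent_id) %in% names(by_id)
  }, logical(1))]
  note("parents_exist", length(missing_parent) == 0L,
       paste(missing_parent, collapse = ", "))

  bad_link <- integer()
  for (b in branches) {
    for (k in b$child_ids) {
      kb <- by_id[[as.character(k)]]
      if (is.null(kb) || is.na(kb$parent_id) || kb$parent_id != b$id) {
        bad_link <- c(bad_link, b$id)
      }
    }
    if (!is.na(b$parent_id)) {
      pb <- by_id[[as.character(b$parent_id)]]
      if (is.null(pb) || !b$id %in% pb$child_ids) bad_link <- c(bad_link, b$id)
    }
  }
  note("links_consistent", length(bad_link) == 0L,
       paste(unique(bad_link), collapse = ", "))

  # acyclicity + reachability: walk parent pointers with a step budget
  cyclic <- integer()
  for (b in branches) {
    seen <- character()
    cur <- b
    while (!is.na(cur$parent_id)) {
      key <- as.character(cur$id)
      if (key %in% seen) { cyclic <- c(cyclic, b$id); break }
      seen <- c(seen, key)
      cur <- by_id[[as.character(cur$parent_id)]]
      if (is.null(cur)) break
    }
  }
  note("acyclic", length(cyclic) == 0L, paste(unique(cyclic), collapse = ", "))

  bad_gen <- ids[vapply(branches, function(b) {
    if (is.na(b$parent_id)) return(FALSE)
    pb <- by_id[[as.character(b$parent_id)]]
    is.null(pb) || b$generation != pb$generation + 1L
  }, logical(1))]
  note("generation_increments", length(bad_gen) == 0L,
       paste(bad_gen, collapse = ", "))

  if (is.finite(connectivity_radius)) {
    far <- ids[vapply(branches, function(b) {
      if (is.na(b$parent_id)) return(FALSE)
      pb <- by_id[[as.character(b$parent_id)]]
      if (is.null(pb)) return(TRUE)
      d <- sqrt(rowSums(sweep(pb$positions, 2, b$positions[1L, ], "-")^2))
      min(d) > connectivity_radius
    }, logical(1))]
    note("child_attached_to_parent", length(far) == 0L,
         paste(far, collapse = ", "))
  }

  dplyr::bind_rows(res)
}

#' Canonical topology signature of an airway tree
#'
#' A nested-parenthesis string that is identical for two trees if and only if
#' their parent/child branching structures are isomorphic (ignoring ids,
#' geometry and radii). Children are sorted by their own signatures, so the
#' result does not depend on child order.
#'
#' @param tree An [airway_tree()].
#' @return A character scalar.
#' @export
tree_topology_signature <- function(tree) {
  sig <- function(id) {
    kids <- tree$branches[[as.character(id)]]$child_ids
    if (length(kids) == 0L) return("()")
    paste0("(", paste(sort(vapply(kids, sig, character(1))), collapse = ""), ")")
  }
  sig(tree$root_id)
}
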
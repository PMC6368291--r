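#' Build the branch model from an unstructured centerline point set
#'
#' Identifies and connects all branches of the airway tree from a cloud of
#' centerline points (typically skeleton voxels): points within
#' `connectivity_radius` are linked, shortcut links are removed by taking a
#' minimum spanning tree of the proximity graph, nodes of degree >= 3 become
#' junctions, and maximal junction-free chains become branches. The root
#' (trachea) is the branch containing the most superior endpoint (largest z
#' in LPS; ties broken by largest radius), and generations are assigned
#' breadth-first from it.
#'
#' A junction point is stored once, as the distal last position of the branch
#' proximal to it; child branches start at their first non-junction point.
#' Leaf chains with fewer than `prune_below` own points hanging off a
#' junction are pruned as skeletonization spurs. If the point set is
#' disconnected at `connectivity_radius`, the largest connected component is
#' kept and the discarded fraction is reported in attribute
#' `"discarded_fraction"`.
#'
#' @param points A data frame with columns `x`, `y`, `z` and optionally
#'   `radius` (as produced by [extract_centerline()]), or an Nx3 matrix.
#' @param connectivity_radius Link distance, mm. Default: 2x the largest
#'   voxel spacing of the source mask when the input carries a `"spacing"`
#'   attribute, otherwise 2.5x the median nearest-neighbour distance.
#' @param prune_below Minimum number of own points for a leaf branch to
#'   survive spur pruning.
#' @return An [airway_tree()]; branch radii are the median per-point radius
#'   when radii are supplied.
#' @export
build_tree <- function(points, connectivity_radius = NULL, prune_below = 3L) {
  P <- rbind3(points)
  storage.mode(P) <- "double"
  if (nrow(P) == 0L) {
    abort("empty centerline point set.", class = "bronchoplan_input_error")
  }
  radii <- if (is.data.frame(points) && "radius" %in% names(points)) {
    as.numeric(points$radius)
  } else {
    rep(NA_real_, nrow(P))
  }
  if (is.null(connectivity_radius)) {
    sp <- attr(points, "spacing")
    connectivity_radius <- if (!is.null(sp)) {
      2 * max(sp)
    } else {
      2.5 * median(nn_dist(P))
    }
  }
  if (!is.finite(connectivity_radius) || connectivity_radius <= 0) {
    abort("`connectivity_radius` must be > 0.", class = "bronchoplan_parameter_error")
  }

  if (nrow(P) == 1L) {
    tr <- airway_tree(list(new_branch(1L, P, generation = 0L, radius = radii[1])))
    attr(tr, "discarded_fraction") <- 0
    return(tr)
  }

  ed <- proximity_edges(P, connectivity_radius)
  g <- igraph::graph_from_edgelist(cbind(ed$i, ed$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(P) - igraph::vcount(g)))

  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  discarded <- 1 - length(keep) / nrow(P)

  # permutation-invariant MST: rank edges by (length, coordinate key)
  sub <- igraph::induced_subgraph(g, keep)
  orig <- keep[as.integer(igraph::V(sub))]
  el <- igraph::as_edgelist(sub, names = FALSE)
  a <- orig[el[, 1]]
  b <- orig[el[, 2]]
  len <- sqrt(rowSums((P[a, , drop = FALSE] - P[b, , drop = FALSE])^2))
  key <- edge_coord_key(P, a, b)
  mst <- igraph::mst(sub, weights = order(order(len, key)))

  # adjacency on original point indices
  mel <- igraph::as_edgelist(mst, names = FALSE)
  adj <- vector("list", nrow(P))
  for (r in seq_len(nrow(mel))) {
    u <- orig[mel[r, 1]]
    v <- orig[mel[r, 2]]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }

  nodes <- keep
  # prune short leaf spurs hanging off junctions, iteratively
  repeat {
    deg <- vapply(seq_len(nrow(P)), function(i) length(adj[[i]]), integer(1))
    leaves <- nodes[deg[nodes] == 1L]
    pruned_any <- FALSE
    for (lf in leaves) {
      path <- walk_chain(adj, deg, lf, adj[[lf]][1])
      last <- path[length(path)]
      if (deg[last] >= 3L && (length(path) - 1L) < prune_below) {
        drop <- path[-length(path)]
        for (d in drop) {
          for (nb in adj[[d]]) adj[[nb]] <- setdiff(adj[[nb]], d)
          adj[[d]] <- integer()
        }
        nodes <- setdiff(nodes, drop)
        deg <- vapply(seq_len(nrow(P)), function(i) length(adj[[i]]), integer(1))
        pruned_any <- TRUE
      }
    }
    if (!pruned_any) break
  }

  deg <- vapply(seq_len(nrow(P)), function(i) length(adj[[i]]), integer(1))
  ends <- nodes[deg[nodes] <= 1L]
  if (length(ends) == 0L) ends <- nodes  # safety: cannot happen on a tree
  ord <- order(-P[ends, 3], -ifelse(is.na(radii[ends]), -Inf, radii[ends]), ends)
  root_node <- ends[ord[1L]]

  # cut the pruned MST into branches at junctions, breadth-first from root
  branches <- list()
  next_id <- 1L
  queue <- list(list(start = root_node, from = NA_integer_,
                     parent = NA_integer_, gen = 0L))
  while (length(queue)) {
    item <- queue[[1L]]
    queue <- queue[-1L]
    path <- item$start
    prev <- item$from
    cur <- item$start
    repeat {
      if (cur != item$start && deg[cur] != 2L) break     # junction or endpoint
      if (cur == item$start && deg[cur] >= 3L) break     # degenerate stub
      nxt <- setdiff(adj[[cur]], prev)
      if (length(nxt) == 0L) break                       # chain end
      prev <- cur
      cur <- nxt[1L]
      path <- c(path, cur)
    }
    id <- next_id
    next_id <- next_id + 1L
    med_r <- if (all(is.na(radii[path]))) NA_real_ else median(radii[path], na.rm = TRUE)
    branches[[id]] <- new_branch(id, P[path, , drop = FALSE],
                                 parent_id = item$parent,
                                 generation = item$gen, radius = med_r)
    if (!is.na(item$parent)) {
      branches[[item$parent]]$child_ids <-
        c(branches[[item$parent]]$child_ids, id)
    }
    tipn <- path[length(path)]
    if (deg[tipn] >= 3L) {
      into <- if (length(path) >= 2L) path[length(path) - 1L] else item$from
      for (nb in setdiff(adj[[tipn]], into)) {
        queue <- c(queue, list(list(start = nb, from = tipn, parent = id,
                                    gen = item$gen + 1L)))
      }
    }
  }

  tr <- airway_tree(branches)
  attr(tr, "discarded_fraction") <- discarded
  tr
}

# follow a degree-2 chain starting at leaf `from` through `nxt` until a node
# of degree != 2; returns the node sequence including both ends
walk_chain <- function(adj, deg, from, nxt) {
  path <- c(from, nxt)
  prev <- from
  cur <- nxt
  while (deg[cur] == 2L) {
    nn <- setdiff(adj[[cur]], prev)
    if (length(nn) == 0L) break
    prev <- cur
    cur <- nn[1L]
    path <- c(path, cur)
  }
  path
}

# all point pairs within radius, via cell binning
proximity_edges <- function(P, radius) {
  cell <- floor(sweep(P, 2, rep(radius, 3), "/"))
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  bins <- split(seq_len(nrow(P)), key)
  cell_of <- setNames(seq_along(bins), names(bins))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ii <- integer()
  jj <- integer()
  for (bn in names(bins)) {
    pts <- bins[[bn]]
    c0 <- as.numeric(strsplit(bn, " ", fixed = TRUE)[[1]])
    cand <- integer()
    for (r in seq_len(nrow(offs))) {
      nb <- paste(c0[1] + offs[r, 1], c0[2] + offs[r, 2], c0[3] + offs[r, 3])
      if (!is.null(bins[[nb]])) cand <- c(cand, bins[[nb]])
    }
    for (p in pts) {
      q <- cand[cand > p]
      if (length(q) == 0L) next
      d2 <- rowSums(sweep(P[q, , drop = FALSE], 2, P[p, ], "-")^2)
      hit <- q[d2 <= radius^2]
      ii <- c(ii, rep(p, length(hit)))
      jj <- c(jj, hit)
    }
  }
  list(i = ii, j = jj)
}

# order-independent lexicographic key of an edge's endpoint coordinates
edge_coord_key <- function(P, a, b) {
  ka <- sprintf("%.9f %.9f %.9f", P[a, 1], P[a, 2], P[a, 3])
  kb <- sprintf("%.9f %.9f %.9f", P[b, 1], P[b, 2], P[b, 3])
  paste(pmin(ka, kb), pmax(ka, kb))
}

nn_dist <- function(P) {
  n <- nrow(P)
  vapply(seq_len(n), function(i) {
    d2 <- rowSums(sweep(P[-i, , drop = FALSE], 2, P[i, ], "-")^2)
    sqrt(min(d2))
  }, numeric(1))
}
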
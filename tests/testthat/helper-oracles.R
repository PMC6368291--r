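# Independent oracles used across tests. These deliberately avoid the code
# paths they check: graph search instead of the parent-walk, ray casting
# instead of mesh bookkeeping, direct distance scans instead of transforms.

# Unique simple path on the tree's position adjacency graph from the trachea
# top to the position closest to `tgt`, by breadth-first search (igraph).
route_graph_oracle <- function(tree, tgt) {
  td <- tidy(tree)
  P <- as.matrix(td[, c("x", "y", "z")])
  idx_of <- split(seq_len(nrow(P)), td$branch_id)
  edges <- c()
  for (b in tree$branches) {
    ii <- idx_of[[as.character(b$id)]]
    if (length(ii) > 1) edges <- c(edges, rbind(ii[-length(ii)], ii[-1]))
    if (!is.na(b$parent_id)) {
      pii <- idx_of[[as.character(b$parent_id)]]
      edges <- c(edges, utils::tail(pii, 1), ii[1])
    }
  }
  g <- igraph::make_graph(edges, n = nrow(P), directed = FALSE)
  d <- sqrt(rowSums(sweep(P, 2, tgt, "-")^2))
  closest <- which.min(d)
  root_first <- idx_of[[as.character(tree$root_id)]][1]
  sp <- igraph::shortest_paths(g, root_first, closest)$vpath[[1]]
  P[as.integer(sp), , drop = FALSE]
}

# Moeller-Trumbore ray casting: is point p inside the closed mesh?
point_in_mesh_oracle <- function(p, mesh, dir = c(0.137, 0.713, 0.687)) {
  dir <- dir / sqrt(sum(dir^2))
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * h)
  ok <- abs(det) > 1e-12
  s <- sweep(a, 2, p, "-") * -1
  u <- rowSums(s * h) / det
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  v <- (q[, 1] * dir[1] + q[, 2] * dir[2] + q[, 3] * dir[3]) / det
  t <- rowSums(e2 * q) / det
  hits <- sum(ok & u >= 0 & v >= 0 & (u + v) <= 1 & t > 1e-9)
  hits %% 2 == 1
}

# minimum distance from point p to polyline S (Nx3)
dist_to_polyline <- function(p, S) {
  dmin <- Inf
  for (i in seq_len(nrow(S) - 1)) {
    a <- S[i, ]; b <- S[i + 1, ]
    u <- b - a
    L2 <- sum(u^2)
    t <- if (L2 == 0) 0 else min(max(sum((p - a) * u) / L2, 0), 1)
    dmin <- min(dmin, sqrt(sum((p - a - t * u)^2)))
  }
  dmin
}

# ball mask centred at the origin on an isotropic grid
ball_mask <- function(r, spacing) {
  n <- ceiling(2 * r / spacing) + 7
  g <- volume_grid(rep(n, 3), rep(spacing, 3), rep(-r - 3 * spacing, 3))
  idx <- as.matrix(expand.grid(seq_len(n), seq_len(n), seq_len(n)))
  P <- index_to_world(g, idx)
  binary_mask(g, array(sqrt(rowSums(P^2)) <= r, dim = g$shape))
}

# solid axis-aligned cylinder mask along z
cylinder_mask <- function(r, len, spacing) {
  nxy <- ceiling(2 * r / spacing) + 7
  nz <- ceiling(len / spacing) + 7
  g <- volume_grid(c(nxy, nxy, nz), rep(spacing, 3),
                   c(-r - 3 * spacing, -r - 3 * spacing, -3 * spacing))
  idx <- as.matrix(expand.grid(seq_len(nxy), seq_len(nxy), seq_len(nz)))
  P <- index_to_world(g, idx)
  inside <- sqrt(P[, 1]^2 + P[, 2]^2) <= r & P[, 3] >= 0 & P[, 3] <= len
  binary_mask(g, array(inside, dim = g$shape))
}

# lateral (cap-free) area of an n-gon tube of ring radius r: the swept mesh
# uses inscribed polygons, whose perimeter is 2 n r sin(pi/n)
ngon_perimeter <- function(r, n) 2 * n * r * sin(pi / n)
ngon_area <- function(r, n) 0.5 * n * r^2 * sin(2 * pi / n)

# a random in-extent target near the tree for property tests
random_target_near <- function(tree) {
  td <- tidy(tree)
  zr <- range(td$z)
  c(runif(1, -80, 80), runif(1, -80, 80), runif(1, zr[1] - 20, zr[2]))
}
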
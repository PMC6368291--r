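test_that("a single straight polyline becomes one root branch", {
  pts <- tibble::tibble(x = 0, y = 0, z = seq(0, -30, by = -1))
  tr <- build_tree(pts, connectivity_radius = 1.5)
  expect_length(tr$branches, 1L)
  expect_true(is.na(tr$branches[[1]]$parent_id))
  expect_identical(tr$branches[[1]]$generation, 0L)
  # proximal end is the most superior point
  expect_equal(unname(tr$branches[[1]]$positions[1, ]), c(0, 0, 0))
  expect_identical(nrow(tr$branches[[1]]$positions), length(pts$z))
})

test_that("a Y of three chains becomes a root with two generation-1 children", {
  down <- seq(0, -20, by = -1)
  arm <- seq_len(15)
  pts <- rbind(
    cbind(0, 0, down),                          # stem, superior at z = 0
    cbind(arm * 0.6, 0, -20 - arm * 0.8),       # left arm from junction
    cbind(-arm * 0.6, 0, -20 - arm * 0.8)       # right arm
  )
  tr <- build_tree(tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3]),
                   connectivity_radius = 1.5)
  expect_length(tr$branches, 3L)
  root <- tr$branches[[as.character(tr$root_id)]]
  expect_length(root$child_ids, 2L)
  gens <- branch_generations(tr)
  expect_setequal(unname(gens), c(0L, 1L, 1L))
  # junction owned by the root: children do not start on the junction point
  jp <- root$positions[nrow(root$positions), ]
  for (k in root$child_ids) {
    expect_gt(sum((tr$branches[[as.character(k)]]$positions[1, ] - jp)^2), 0)
  }
  # every retained point belongs to exactly one branch
  expect_identical(sum(vapply(tr$branches, function(b) nrow(b$positions),
                              integer(1))),
                   nrow(pts))
})

test_that("skeleton of a voxelized depth-3 phantom recovers the 15-branch topology", {
  truth <- generate_airway_tree(phantom_params(depth = 3))
  finest <- 9 * 0.79^3
  g <- grid_for_tree(truth, finest / 2)
  mask <- voxelize_tree(truth, g)
  cl <- extract_centerline(mask)
  tr <- build_tree(cl)
  expect_length(tr$branches, 15L)
  expect_length(terminal_branches(tr), 8L)
  expect_identical(tree_topology_signature(tr), tree_topology_signature(truth))
  expect_true(all(validate_tree(tr, connectivity_radius = 2 * max(g$spacing))$pass))
})

test_that("generations follow a breadth-first numbering from the trachea", {
  tr <- generate_airway_tree(phantom_params(depth = 2))
  gens <- branch_generations(tr)
  expect_identical(sort(unname(gens)), c(0L, 1L, 1L, 2L, 2L, 2L, 2L))
  expect_identical(max(gens), 2L)
  one <- generate_airway_tree(phantom_params(depth = 0))
  expect_identical(unname(branch_generations(one)), 0L)
  # recomputed generations agree with an independent parent-walk
  walk_gen <- function(tree, id) {
    g <- 0L
    b <- tree$branches[[as.character(id)]]
    while (!is.na(b$parent_id)) {
      g <- g + 1L
      b <- tree$branches[[as.character(b$parent_id)]]
    }
    g
  }
  for (id in names(tr$branches)) {
    expect_identical(unname(gens[[id]]), walk_gen(tr, as.integer(id)))
  }
})

test_that("build_tree is invariant under permutation of the input points", {
  truth <- generate_airway_tree(phantom_params(depth = 2))
  g <- grid_for_tree(truth, 2)
  cl <- extract_centerline(voxelize_tree(truth, g))
  t1 <- build_tree(cl)
  set.seed(9)
  perm <- sample(nrow(cl))
  cl2 <- cl[perm, ]
  attr(cl2, "spacing") <- attr(cl, "spacing")
  t2 <- build_tree(cl2)
  expect_identical(tree_topology_signature(t1), tree_topology_signature(t2))
  # same point partition: sorted per-branch position sets agree
  canon <- function(tr) {
    sets <- lapply(tr$branches, function(b) {
      m <- round(b$positions, 9)
      paste(sort(paste(m[, 1], m[, 2], m[, 3])), collapse = ";")
    })
    sort(unlist(sets))
  }
  expect_identical(unname(canon(t1)), unname(canon(t2)))
})

test_that("disconnected point sets keep the largest component and report it", {
  pts <- tibble::tibble(
    x = c(rep(0, 20), rep(50, 5)),
    y = 0,
    z = c(seq(0, -19), seq(0, -4))
  )
  tr <- build_tree(pts, connectivity_radius = 1.5)
  expect_length(tr$branches, 1L)
  expect_equal(attr(tr, "discarded_fraction"), 5 / 25)
  expect_error(build_tree(pts[0, ]), class = "bronchoplan_input_error")
})

test_that("validate_tree flags constructed invariant violations", {
  good <- generate_airway_tree(phantom_params(depth = 1))
  expect_true(all(validate_tree(good)$pass))

  two_roots <- good
  two_roots$branches[["2"]]$parent_id <- NA_integer_
  rep1 <- validate_tree(two_roots)
  expect_false(rep1$pass[rep1$check == "single_root"])

  cyclic <- good
  cyclic$branches[["1"]]$parent_id <- 3L
  rep2 <- validate_tree(cyclic)
  expect_false(rep2$pass[rep2$check == "acyclic"])

  bad_gen <- good
  bad_gen$branches[["3"]]$generation <- 5L
  rep3 <- validate_tree(bad_gen)
  expect_false(rep3$pass[rep3$check == "generation_increments"])
})

test_that("short leaf spurs hanging off junctions are pruned", {
  down <- seq(0, -20, by = -1)
  arm <- seq_len(12)
  pts <- rbind(
    cbind(0, 0, down),
    cbind(arm * 0.7, 0, -20 - arm * 0.7),
    cbind(-arm * 0.7, 0, -20 - arm * 0.7),
    cbind(0, c(0.9, 1.8), -20)  # 2-point spur at the junction
  )
  tr <- build_tree(tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3]),
                   connectivity_radius = 1.5, prune_below = 3L)
  expect_length(tr$branches, 3L)
})
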
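test_that("closest centerline point matches an exhaustive scan", {
  tr <- generate_airway_tree(phantom_params(depth = 2, angle_jitter = 3, seed = 5))
  td <- tidy(tr)
  P <- as.matrix(td[, c("x", "y", "z")])
  set.seed(21)
  for (i in 1:20) {
    tgt <- random_target_near(tr)
    got <- closest_centerline_point(tr, tgt)
    d <- sqrt(rowSums(sweep(P, 2, tgt, "-")^2))
    expect_equal(got$distance, min(d))
    expect_equal(unname(got$position), unname(P[which.min(d), ]))
  }
  # a target exactly on a centerline point has distance zero
  on_line <- as.numeric(td[57, c("x", "y", "z")])
  hit <- closest_centerline_point(tr, on_line)
  expect_equal(hit$distance, 0)
})

test_that("distance ties break to the smallest branch id, then index", {
  # two parallel vertical branches hanging off a horizontal root
  root <- new_branch(1L, cbind(seq(-5, 5), 0, 0), child_ids = c(2L, 3L),
                     generation = 0L, radius = 3)
  left <- new_branch(2L, cbind(-2, seq_len(5), -1), parent_id = 1L,
                     generation = 1L, radius = 2)
  right <- new_branch(3L, cbind(2, seq_len(5), -1), parent_id = 1L,
                      generation = 1L, radius = 2)
  tr <- airway_tree(list(root, left, right))
  # (0, 5, -1) is exactly 2 mm from the tips of branches 2 and 3, and
  # farther from every root position: the smaller branch id must win
  got <- closest_centerline_point(tr, c(0, 5, -1))
  expect_identical(got$branch_id, 2L)
  expect_identical(got$index, 5L)
  expect_equal(got$distance, 2)
  expect_error(closest_centerline_point(structure(list(branches = list()),
                                                  class = "airway_tree"),
                                        c(0, 0, 0)),
               class = "bronchoplan_input_error")
})

test_that("a target beside the trachea yields a pure trachea route", {
  tr <- generate_airway_tree(phantom_params(depth = 2))
  top <- trachea_top(tr)
  tgt <- top + c(25, 0, -40)  # level with the trachea midsection
  rt <- route_to_target(tr, tgt)
  expect_identical(unique(rt$positions$branch_id), tr$root_id)
  expect_equal(as.numeric(rt$positions[1, c("x", "y", "z")]), unname(top))
  cl <- closest_centerline_point(tr, tgt)
  expect_equal(rt$gap_mm, cl$distance)
})

test_that("routes equal the graph-search shortest path on random phantoms", {
  set.seed(42)
  n_ok <- 0L
  n_cases <- 40L
  for (i in seq_len(n_cases)) {
    d <- sample(1:4, 1)
    tr <- generate_airway_tree(phantom_params(depth = d, angle_jitter = 5,
                                              seed = i))
    tgt <- random_target_near(tr)
    got <- as.matrix(route_to_target(tr, tgt)$positions[, c("x", "y", "z")])
    oracle <- route_graph_oracle(tr, tgt)
    if (isTRUE(all.equal(got, oracle, check.attributes = FALSE,
                         tolerance = 1e-12))) {
      n_ok <- n_ok + 1L
    }
  }
  expect_identical(n_ok, n_cases)
})

test_that("every route starts at the trachea top with non-decreasing generations", {
  set.seed(7)
  for (i in 1:10) {
    tr <- generate_airway_tree(phantom_params(depth = 3, angle_jitter = 4,
                                              seed = i))
    rt <- route_to_target(tr, random_target_near(tr))
    expect_equal(as.numeric(rt$positions[1, c("x", "y", "z")]),
                 unname(trachea_top(tr)))
    expect_false(is.unsorted(rt$positions$generation))
    # junction points appear exactly once
    P <- as.matrix(rt$positions[, c("x", "y", "z")])
    expect_identical(anyDuplicated(P), 0L)
  }
})

test_that("redefining the same target reproduces the identical route", {
  tr <- generate_airway_tree(phantom_params(depth = 2))
  tgt <- target("lesion", c(30, 10, -150), created = "")
  r1 <- route_to_target(tr, tgt)
  r2 <- route_to_target(tr, tgt)
  expect_identical(r1$positions, r2$positions)
  expect_identical(r1$gap_mm, r2$gap_mm)
})

test_that("route metrics report length, branch count, generation and gap", {
  # straight 100 mm trachea: route to a point near the distal end
  tr <- generate_airway_tree(phantom_params(depth = 0, trachea_length = 100))
  tip <- tidy(tr)
  tgt <- as.numeric(tip[nrow(tip), c("x", "y", "z")]) + c(2, 0, 0)
  m <- glance(route_to_target(tr, tgt))
  expect_equal(m$length_mm, 100, tolerance = 1e-9)
  expect_identical(m$n_branches, 1L)
  expect_equal(m$gap_mm, 2)

  # branch count along a route to a generation-g target is g + 1
  tr3 <- generate_airway_tree(phantom_params(depth = 3))
  td <- tidy(tr3)
  for (g in 0:3) {
    leafward <- td[td$generation == g, ]
    tgt_g <- as.numeric(leafward[nrow(leafward), c("x", "y", "z")])
    mg <- glance(route_to_target(tr3, tgt_g))
    expect_identical(mg$n_branches, g + 1L)
    expect_identical(mg$max_generation, g)
  }

  # degenerate single-point route has zero length
  one <- airway_tree(list(new_branch(1L, matrix(c(0, 0, 0), 1), radius = 2)))
  m1 <- glance(route_to_target(one, c(5, 0, 0)))
  expect_equal(m1$length_mm, 0)
})
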
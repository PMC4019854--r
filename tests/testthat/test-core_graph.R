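test_that("connectivity matrix validation accepts valid input and rejects each violated invariant", {
  w <- matrix(c(0, 5, 0, 5, 0, 2, 0, 2, 0), 3, 3)
  m <- connectivity_matrix(w)
  expect_s3_class(m, "connectivity_matrix")
  expect_identical(m$weights[1, 2], 5)

  bad <- w; bad[1, 2] <- 2; bad[2, 1] <- 3
  expect_error(connectivity_matrix(bad), "asymmetric")
  bad <- w; bad[2, 2] <- 5
  expect_error(connectivity_matrix(bad), "diagonal")
  bad <- w; bad[1, 3] <- bad[3, 1] <- -1
  expect_error(connectivity_matrix(bad), "negative")
  expect_error(connectivity_matrix(matrix(0, 1, 1)), "at least 2 nodes")
  expect_error(connectivity_matrix(matrix(0, 2, 3)), "square")
})

test_that("density follows the ordered-pair convention 2E/(N(N-1))", {
  cyc4 <- binary_graph(adj_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))))
  expect_equal(compute_density(cyc4), 2 / 3)
  expect_equal(compute_density(binary_graph(complete_adj(5))), 1.0)
  expect_equal(compute_density(binary_graph(matrix(0, 6, 6))), 0.0)
})

test_that("max_density counts strictly positive edges", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 5; w[2, 3] <- w[3, 2] <- 2
  expect_equal(max_density(connectivity_matrix(w)), 2 / 3)
  full <- matrix(1, 4, 4); diag(full) <- 0
  expect_equal(max_density(connectivity_matrix(full)), 1.0)
  expect_equal(max_density(connectivity_matrix(matrix(0, 4, 4))), 0.0)
})

test_that("thresholding keeps the top-weighted edges with the stated budget", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 10; w[1, 3] <- 8; w[1, 4] <- 6; w[2, 3] <- 4; w[2, 4] <- 2; w[3, 4] <- 1
  w <- w + t(w)
  m <- connectivity_matrix(w)
  g <- threshold_to_density(m, 0.5)
  expect_equal(sum(g$adjacency) / 2, 3)
  expect_equal(g$adjacency[1, 2], 1)
  expect_equal(g$adjacency[1, 3], 1)
  expect_equal(g$adjacency[1, 4], 1)
  expect_equal(g$adjacency[2, 3], 0)

  # at max density every positive edge survives, binarized
  gmax <- threshold_to_density(m, max_density(m))
  expect_equal(gmax$adjacency, (w > 0) * 1, ignore_attr = TRUE)

  expect_error(threshold_to_density(m, 1.5), "infeasible density")
})

test_that("tied weights break deterministically by ascending index pair", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[1, 3] <- w[2, 3] <- 5
  w <- pmax(w, t(w))
  g <- threshold_to_density(connectivity_matrix(w), 1 / 3)
  expect_equal(sum(g$adjacency) / 2, 1)
  expect_equal(g$adjacency[1, 2], 1)
})

test_that("thresholded graphs are nested, exact-count and deterministic across random matrices", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(5:12, 1)
    m <- connectivity_matrix(random_weight_matrix(n, 0.7, max_w = 20))
    md <- max_density(m)
    n_possible <- n * (n - 1) / 2
    dgrid <- seq(0.1, 1, by = 0.15) * md
    prev <- NULL
    for (d in dgrid) {
      g <- threshold_to_density(m, d)
      expect_equal(sum(g$adjacency) / 2, floor(d * n_possible + 0.5))
      # density matches the target to within the rounding of one edge
      expect_lt(abs(compute_density(g) - d), 2 / (n * (n - 1)) + 1e-12)
      if (!is.null(prev)) expect_true(all(g$adjacency >= prev))
      prev <- g$adjacency
      g2 <- threshold_to_density(m, d)
      expect_identical(g$adjacency, g2$adjacency)
    }
  }
})

test_that("connected components partition the node set", {
  g <- binary_graph(adj_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3),
                                           c(4, 5), c(5, 6), c(4, 6))))
  comps <- connected_components(g)
  expect_length(comps, 2)
  expect_equal(comps[[1]], 1:3)
  expect_equal(comps[[2]], 4:6)

  path <- binary_graph(path_adj(5))
  expect_equal(connected_components(path), list(1:5))

  empty <- binary_graph(matrix(0, 4, 4))
  expect_equal(lengths(connected_components(empty)), rep(1L, 4))
  expect_equal(sort(unlist(connected_components(empty))), 1:4)

  # property: disjoint cover on random graphs
  set.seed(21)
  for (rep in 1:20) {
    a <- random_adjacency(8, 0.2)
    comps <- connected_components(binary_graph(a))
    expect_equal(sort(unlist(comps)), 1:8)
    expect_equal(oracle_components(a),
                 rep(seq_along(comps), lengths(comps))[order(unlist(comps))])
  }
})

test_that("largest connected component extraction and its tie-break", {
  tri_iso <- binary_graph(adj_from_edges(4, list(c(1, 2), c(2, 3), c(1, 3))))
  lcc <- largest_connected_component(tri_iso)
  expect_equal(attr(lcc, "node_index"), 1:3)

  tri_edge <- binary_graph(adj_from_edges(5, list(c(1, 2), c(2, 3), c(1, 3), c(4, 5))))
  expect_equal(attr(largest_connected_component(tri_edge), "node_index"), 1:3)

  two_edges <- binary_graph(adj_from_edges(4, list(c(1, 2), c(3, 4))))
  expect_equal(attr(largest_connected_component(two_edges), "node_index"), 1:2)

  expect_error(largest_connected_component(binary_graph(matrix(0, 3, 3))),
               "degenerate")
})

test_that("degrees are adjacency row sums", {
  expect_equal(degrees(binary_graph(star_adj(3))), c(3L, 1L, 1L, 1L))
  expect_equal(degrees(binary_graph(complete_adj(4))), rep(3L, 4))
  expect_equal(degrees(binary_graph(matrix(0, 3, 3))), rep(0L, 3))
})
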
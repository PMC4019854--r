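test_that("shortest path lengths handle paths, cliques and disconnection", {
  p3 <- binary_graph(path_adj(3))
  d <- all_pairs_shortest_path_lengths(p3)
  expect_equal(d[1, 3], 2)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)

  two <- binary_graph(adj_from_edges(4, list(c(1, 2), c(3, 4))))
  expect_equal(all_pairs_shortest_path_lengths(two)[1, 3], Inf)

  k5 <- all_pairs_shortest_path_lengths(binary_graph(complete_adj(5)))
  expect_true(all(k5[upper.tri(k5)] == 1))
})

test_that("hand-derived small-graph metric values", {
  tri <- binary_graph(complete_adj(3))
  p3 <- binary_graph(path_adj(3))
  expect_equal(mean_clustering_coefficient(tri), 1.0)
  expect_equal(mean_clustering_coefficient(p3), 0.0)
  expect_equal(characteristic_path_length(tri), 1.0)
  expect_equal(characteristic_path_length(p3), 4 / 3)
  expect_equal(global_efficiency(p3), 5 / 6)
  expect_equal(local_efficiency(p3), 0.0)
  expect_equal(local_efficiency(binary_graph(complete_adj(4))), 1.0)

  # CPL ignores nodes outside the largest component
  tri_iso <- binary_graph(adj_from_edges(4, list(c(1, 2), c(2, 3), c(1, 3))))
  expect_equal(characteristic_path_length(tri_iso), 1.0)
  expect_equal(largest_component_size(tri_iso)$size, 3L)
  expect_equal(largest_component_size(tri_iso)$fraction, 0.75)
  expect_equal(largest_component_size(binary_graph(matrix(0, 4, 4)))$size, 1L)
})

test_that("assortativity matches its closed forms and flags regular graphs", {
  expect_true(is.na(assortativity(binary_graph(complete_adj(4)))))
  expect_equal(assortativity(binary_graph(star_adj(4))), -1.0)
  expect_error(assortativity(binary_graph(matrix(0, 3, 3))), "degenerate")
})

test_that("rich-club coefficient at its boundary levels", {
  k4 <- binary_graph(complete_adj(4))
  expect_equal(rich_club_coefficient(k4, 3), 1.0)
  star <- binary_graph(star_adj(4))
  expect_true(is.na(rich_club_coefficient(star, 2)))
  set.seed(5)
  for (rep in 1:20) {
    g <- binary_graph(random_adjacency(sample(4:9, 1), runif(1, 0.2, 0.8)))
    expect_equal(rich_club_coefficient(g, 0), compute_density(g))
  }
})

test_that("all seven metrics agree with exhaustive oracles on random graphs", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(4:10, 1)
    a <- random_adjacency(n, runif(1, 0.15, 0.9))
    g <- binary_graph(a)
    expect_equal(mean_clustering_coefficient(g), oracle_clustering(a),
                 tolerance = 1e-12)
    expect_equal(global_efficiency(g), oracle_global_efficiency(a),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(g), oracle_local_efficiency(a),
                 tolerance = 1e-12)
    expect_equal(largest_component_size(g)$fraction,
                 oracle_largest_component_fraction(a), tolerance = 1e-12)
    if (sum(a) > 0) {
      expect_equal(characteristic_path_length(g), oracle_cpl(a),
                   tolerance = 1e-12)
      expect_equal(assortativity(g), oracle_assortativity(a),
                   tolerance = 1e-12)
    }
    for (k in 0:max(rowSums(a)))
      expect_equal(rich_club_coefficient(g, k), oracle_rich_club(a, k),
                   tolerance = 1e-12)
  }
})

test_that("metrics agree with igraph on random graphs", {
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    a <- random_adjacency(n, 0.5)
    g <- binary_graph(a)
    ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(mean_clustering_coefficient(g),
                 mean(igraph::transitivity(ig, type = "localundirected",
                                           isolates = "zero")),
                 tolerance = 1e-12)
    d <- all_pairs_shortest_path_lengths(g)
    expect_equal(d, igraph::distances(ig), ignore_attr = TRUE,
                 tolerance = 1e-12)
    av <- assortativity(g)
    if (!is.na(av))
      expect_equal(av, igraph::assortativity_degree(ig), tolerance = 1e-12)
  }
})

test_that("adding an edge never worsens path length or global efficiency", {
  set.seed(303)
  for (rep in 1:20) {
    n <- 8
    a <- random_adjacency(n, 0.5)
    miss <- which(upper.tri(a) & a == 0, arr.ind = TRUE)
    if (nrow(miss) == 0 || sum(a) == 0) next
    e <- miss[sample.int(nrow(miss), 1), ]
    a2 <- a; a2[e[1], e[2]] <- a2[e[2], e[1]] <- 1
    g <- binary_graph(a); g2 <- binary_graph(a2)
    expect_gte(global_efficiency(g2), global_efficiency(g) - 1e-12)
    # compare CPL on a fixed connected node set
    comp <- oracle_components(a)
    if (max(tabulate(comp)) == n)
      expect_lte(characteristic_path_length(g2),
                 characteristic_path_length(g) + 1e-12)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(404)
  for (rep in 1:10) {
    n <- 9
    a <- random_adjacency(n, 0.4)
    if (sum(a) == 0) next
    perm <- sample.int(n)
    ap <- a[perm, perm]
    g <- binary_graph(a); gp <- binary_graph(ap)
    expect_equal(mean_clustering_coefficient(g), mean_clustering_coefficient(gp))
    expect_equal(global_efficiency(g), global_efficiency(gp))
    expect_equal(local_efficiency(g), local_efficiency(gp))
    expect_equal(characteristic_path_length(g), characteristic_path_length(gp))
    expect_equal(assortativity(g), assortativity(gp))
    expect_equal(largest_component_size(g)$size, largest_component_size(gp)$size)
    expect_equal(rich_club_coefficient(g, 2), rich_club_coefficient(gp, 2))
  }
})
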
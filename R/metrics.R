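# The seven binary undirected network summary measures, plus the shortest
# path helper they share. Undefined values (vanishing denominators, rich club
# with fewer than two qualifying nodes) are reported as NA_real_ so that
# curve code can carry gaps explicitly.

#' All-pairs shortest path lengths
#'
#' Hop-count distances between every pair of nodes, computed by simultaneous
#' breadth-first expansion from all sources (level-synchronous boolean matrix
#' products). `Inf` marks pairs in different components.
#'
#' @param g A [binary_graph()].
#' @return N x N symmetric numeric matrix with zero diagonal; entry (i, j) is
#'   the minimum number of edges on a path from i to j, or `Inf` if none
#'   exists.
#' @export
all_pairs_shortest_path_lengths <- function(g) {
  a <- g$adjacency > 0
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reached <- diag(TRUE, n)
  frontier <- reached
  step <- 0L
  repeat {
    step <- step + 1L
    nxt <- (frontier %*% a) > 0
    new <- nxt & !reached
    if (!any(new)) break
    d[new] <- step
    reached <- reached | new
    frontier <- new
  }
  dimnames(d) <- dimnames(g$adjacency)
  d
}

#' Mean clustering coefficient
#'
#' Per-node clustering `C_i = 2 e_i / (k_i (k_i - 1))`, where `k_i` is the
#' degree of node i and `e_i` the number of edges among its neighbors,
#' averaged over all N nodes. Nodes of degree < 2 have a vanishing
#' denominator and contribute `C_i = 0`.
#'
#' @param g A [binary_graph()].
#' @return Real in \[0, 1\].
#' @export
mean_clustering_coefficient <- function(g) {
  a <- g$adjacency
  k <- rowSums(a)
  tri2 <- diag(a %*% a %*% a)   # 2 * e_i at each node
  ci <- ifelse(k >= 2, tri2 / (k * (k - 1)), 0)
  mean(ci)
}

#' Characteristic path length
#'
#' Mean shortest-path hop count over all ordered pairs of distinct nodes.
#' The measure is only defined for connected graphs, so the largest connected
#' component is extracted first and the average taken within it.
#'
#' @param g A [binary_graph()] with at least one edge.
#' @return Real >= 1, or `NA` if the largest component has fewer than two
#'   nodes.
#' @export
characteristic_path_length <- function(g) {
  lcc <- largest_connected_component(g)
  n <- nrow(lcc$adjacency)
  if (n < 2L) return(NA_real_)
  d <- all_pairs_shortest_path_lengths(lcc)
  sum(d[upper.tri(d)]) * 2 / (n * (n - 1))
}

#' Size of the largest connected component
#'
#' @param g A [binary_graph()].
#' @return List with `size` (integer node count of the largest component;
#'   1 for an edgeless graph, whose components are singletons) and `fraction`
#'   (`size / N`).
#' @export
largest_component_size <- function(g) {
  sizes <- lengths(connected_components(g))
  size <- max(sizes)
  list(size = as.integer(size), fraction = size / nrow(g$adjacency))
}

#' Degree assortativity
#'
#' Measures how preferentially nodes of similar degree connect. With
#' `(j_i, k_i)` the endpoint degrees of each undirected edge i and E the
#' number of edges:
#' \deqn{A = \frac{E^{-1}\sum_i j_i k_i - [E^{-1}\sum_i \frac{1}{2}(j_i+k_i)]^2}{
#'            E^{-1}\sum_i \frac{1}{2}(j_i^2+k_i^2) - [E^{-1}\sum_i \frac{1}{2}(j_i+k_i)]^2}}
#' This is the Pearson correlation of degrees across edge ends. When all
#' edge-endpoint degrees are identical (e.g. any regular graph) the
#' denominator vanishes and `NA` is returned.
#'
#' @param g A [binary_graph()] with at least one edge.
#' @return Real in \[-1, 1\], or `NA` when undefined.
#' @export
assortativity <- function(g) {
  a <- g$adjacency
  if (sum(a) == 0)
    stop("degenerate graph: no edges, assortativity undefined", call. = FALSE)
  deg <- rowSums(a)
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  dj <- deg[idx[, 1]]
  dk <- deg[idx[, 2]]
  e <- nrow(idx)
  m1 <- sum(dj * dk) / e
  mh <- sum((dj + dk) / 2) / e
  m2 <- sum((dj^2 + dk^2) / 2) / e
  denom <- m2 - mh^2
  if (abs(denom) < 1e-12) return(NA_real_)
  (m1 - mh^2) / denom
}

#' Global efficiency
#'
#' Mean of the inverse shortest-path length `1 / L_ij` over all ordered pairs
#' of distinct nodes, with `1 / Inf = 0` for disconnected pairs. Defined for
#' both connected and unconnected graphs; no component extraction is applied.
#'
#' @param g A [binary_graph()] with N >= 2.
#' @return Real in \[0, 1\].
#' @export
global_efficiency <- function(g) {
  n <- nrow(g$adjacency)
  if (n < 2L) stop("global efficiency needs at least 2 nodes", call. = FALSE)
  d <- all_pairs_shortest_path_lengths(g)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Fault tolerance of the network: for each node i, the global efficiency of
#' the subgraph induced on the neighbors of i (communication efficiency among
#' the neighbors if i itself were removed), averaged over all N nodes. Nodes
#' with fewer than two neighbors contribute 0.
#'
#' @param g A [binary_graph()].
#' @return Real in \[0, 1\].
#' @export
local_efficiency <- function(g) {
  a <- g$adjacency
  n <- nrow(a)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2L) return(0)
    global_efficiency(binary_graph(a[nb, nb, drop = FALSE]))
  }, numeric(1))
  mean(vals)
}

#' Rich-club coefficient
#'
#' Quantifies how preferentially high-degree ("rich") nodes connect to one
#' another. With `N(G, k)` the nodes of degree >= k (degree measured in the
#' full graph) and `E(G, k)` the edges of the subgraph induced on them:
#' `R(G, k) = 2 |E(G, k)| / (|N(G, k)| (|N(G, k)| - 1))`, i.e. the density of
#' the rich-node subgraph, so `R(G, 0)` equals the graph density.
#'
#' @param g A [binary_graph()].
#' @param k Integer degree level >= 0.
#' @return Real in \[0, 1\], or `NA` when fewer than two nodes have degree
#'   >= k.
#' @export
rich_club_coefficient <- function(g, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    stop("k must be a single nonnegative integer", call. = FALSE)
  deg <- rowSums(g$adjacency)
  rich <- which(deg >= k)
  nr <- length(rich)
  if (nr < 2L) return(NA_real_)
  sub <- g$adjacency[rich, rich, drop = FALSE]
  2 * sum(sub[upper.tri(sub)]) / (nr * (nr - 1))
}

#' Names of the density-curve network metrics
#'
#' The registry of metric names accepted by [metric_curve()] and
#' [run_pipeline()] (the rich-club coefficient is handled separately via
#' [rich_club_curve()] because it sweeps degree level rather than density).
#'
#' @return Character vector of metric names.
#' @export
metric_names <- function() {
  c("clustering", "char_path_length", "largest_component_size",
    "assortativity", "global_efficiency", "local_efficiency")
}

metric_function <- function(name) {
  switch(name,
    clustering = mean_clustering_coefficient,
    char_path_length = function(g) {
      if (sum(g$adjacency) == 0) NA_real_ else characteristic_path_length(g)
    },
    largest_component_size = function(g) largest_component_size(g)$fraction,
    assortativity = function(g) {
      if (sum(g$adjacency) == 0) NA_real_ else assortativity(g)
    },
    global_efficiency = global_efficiency,
    local_efficiency = local_efficiency,
    stop(sprintf("unknown metric '%s'", name), call. = FALSE)
  )
}
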
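#' Construct a binary undirected graph
#'
#' A `binary_graph` is the result of density thresholding: a symmetric 0/1
#' adjacency matrix with zero diagonal, plus the node labels and the realized
#' graph density.
#'
#' @param adjacency Square symmetric 0/1 numeric matrix with zero diagonal.
#' @param node_labels Optional character vector of node names.
#' @return An object of class `binary_graph` with elements `adjacency`,
#'   `node_labels` and `density` (the value of [compute_density()] on the
#'   adjacency).
#' @export
binary_graph <- function(adjacency, node_labels = NULL) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be square", call. = FALSE)
  if (any(!adjacency %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1", call. = FALSE)
  if (any(adjacency != t(adjacency)))
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(adjacency) != 0))
    stop("adjacency diagonal must be zero", call. = FALSE)
  if (is.null(node_labels)) {
    node_labels <- if (!is.null(rownames(adjacency))) rownames(adjacency)
                   else default_node_labels(nrow(adjacency))
  }
  node_labels <- as.character(node_labels)
  dimnames(adjacency) <- list(node_labels, node_labels)
  g <- structure(list(adjacency = adjacency, node_labels = node_labels,
                      density = NA_real_),
                 class = "binary_graph")
  g$density <- compute_density(g)
  g
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges, density %.4f\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$density))
  invisible(x)
}

#' Graph density
#'
#' Density of an undirected graph under the ordered-pair convention
#' `D(G) = 2 E / (N (N - 1))`, where `E` counts each undirected edge once.
#' With this convention a complete graph has density 1.
#'
#' @param g A [binary_graph()].
#' @return Real in \[0, 1\].
#' @export
#' @examples
#' a <- matrix(0, 4, 4); a[cbind(1:4, c(2, 3, 4, 1))] <- 1
#' a <- pmax(a, t(a))
#' compute_density(binary_graph(a))  # 4-cycle: 2*4 / (4*3) = 2/3
compute_density <- function(g) {
  a <- g$adjacency
  n <- nrow(a)
  2 * sum(a[upper.tri(a)]) / (n * (n - 1))
}

#' Cumulative density thresholding with binarization
#'
#' Retains the top-weighted edges of a streamline-count matrix until the edge
#' budget implied by `target_density` is met, then sets surviving weights to
#' 1. The edge budget is `round_half_up(target_density * N (N - 1) / 2)`.
#' Edges are ranked by weight descending, ties broken by (i, j) index pair
#' ascending, giving a deterministic total order; thresholded graphs are
#' therefore nested across increasing densities. Zero-weight pairs are never
#' selected.
#'
#' @param m A [connectivity_matrix()].
#' @param target_density Requested density in \[0, [max_density()]\].
#' @return A [binary_graph()] with exactly the budgeted number of edges.
#' @export
#' @examples
#' w <- matrix(0, 4, 4)
#' w[upper.tri(w)] <- c(10, 8, 4, 6, 2, 1)  # (1,2) (1,3) (2,3) (1,4) (2,4) (3,4)
#' w <- w + t(w)
#' g <- threshold_to_density(connectivity_matrix(w), 0.5)
#' sum(g$adjacency) / 2  # 3 edges kept
threshold_to_density <- function(m, target_density) {
  validate_matrix(m)
  if (!is.numeric(target_density) || length(target_density) != 1L ||
      is.na(target_density) || target_density < 0)
    stop("target_density must be a single nonnegative number", call. = FALSE)
  w <- m$weights
  n <- nrow(w)
  n_possible <- n * (n - 1) / 2
  md <- max_density(m)
  if (target_density > md + 1e-12)
    stop(sprintf(
      "infeasible density %.6g: maximum achievable for this matrix is %.6g",
      target_density, md), call. = FALSE)
  n_edges <- round_half_up(min(target_density, md) * n_possible)
  pairs <- upper_pairs(n)
  weight <- w[pairs]
  pos <- weight > 0
  pairs <- pairs[pos, , drop = FALSE]
  weight <- weight[pos]
  if (n_edges > length(weight))
    stop(sprintf(
      "edge budget %d exceeds the %d positive edges available", n_edges,
      length(weight)), call. = FALSE)
  a <- matrix(0, n, n)
  if (n_edges > 0L) {
    ord <- order(-weight, pairs[, 1], pairs[, 2])
    keep <- pairs[ord[seq_len(n_edges)], , drop = FALSE]
    a[keep] <- 1
    a[keep[, c(2, 1), drop = FALSE]] <- 1
  }
  binary_graph(a, m$node_labels)
}

#' Connected components of a binary graph
#'
#' Partitions the node indices into maximal sets within which every pair of
#' nodes is joined by a path. Components are returned ordered by their
#' smallest node index.
#'
#' @param g A [binary_graph()].
#' @return List of strictly increasing integer vectors; a disjoint cover of
#'   `1:N`.
#' @export
connected_components <- function(g) {
  a <- g$adjacency > 0
  n <- nrow(a)
  comp <- integer(n)           # 0 = unassigned
  n_comp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    n_comp <- n_comp + 1L
    frontier <- s
    comp[s] <- n_comp
    while (length(frontier) > 0L) {
      nb <- which(colSums(a[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- n_comp
      frontier <- nb
    }
  }
  lapply(seq_len(n_comp), function(k) which(comp == k))
}

#' Largest connected component
#'
#' Induced subgraph on the component with the greatest number of nodes; ties
#' are broken in favor of the component containing the smallest node index.
#'
#' @param g A [binary_graph()] with at least one edge.
#' @return A [binary_graph()] on the component's nodes, with node labels
#'   carried over. The node indices are also attached as attribute
#'   `"node_index"`.
#' @export
largest_connected_component <- function(g) {
  if (sum(g$adjacency) == 0)
    stop("degenerate graph: no edges, largest connected component undefined",
         call. = FALSE)
  comps <- connected_components(g)
  sizes <- lengths(comps)
  # components are ordered by smallest member, so which.max applies the
  # smallest-index tie-break
  idx <- comps[[which.max(sizes)]]
  sub <- binary_graph(g$adjacency[idx, idx, drop = FALSE], g$node_labels[idx])
  attr(sub, "node_index") <- idx
  sub
}

#' Node degrees
#'
#' @param g A [binary_graph()].
#' @return Integer vector: the number of neighbors of each node (row sums of
#'   the adjacency matrix).
#' @export
degrees <- function(g) {
  as.integer(rowSums(g$adjacency))
}
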
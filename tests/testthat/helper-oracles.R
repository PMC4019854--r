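# Independent exhaustive implementations of the graph metrics, used as
# oracles. Deliberately naive: explicit loops, Floyd-Warshall paths, direct
# formula evaluation — sharing no code with the package internals.

oracle_floyd_warshall <- function(a) {
  n <- nrow(a)
  d <- ifelse(a > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_components <- function(a) {
  d <- oracle_floyd_warshall(a)
  n <- nrow(a)
  comp <- integer(n)
  nc <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      nc <- nc + 1L
      comp[is.finite(d[i, ])] <- nc
    }
  }
  comp
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) { ci[i] <- 0; next }
    e <- 0
    for (u in nb) for (v in nb) if (u < v && a[u, v] > 0) e <- e + 1
    ci[i] <- 2 * e / (k * (k - 1))
  }
  mean(ci)
}

oracle_cpl <- function(a) {
  comp <- oracle_components(a)
  sizes <- tabulate(comp)
  # components are numbered in order of their smallest node, so which.max's
  # first-maximum rule applies the smallest-index tie-break
  idx <- which(comp == which.max(sizes))
  if (length(idx) < 2) return(NA_real_)
  d <- oracle_floyd_warshall(a[idx, idx, drop = FALSE])
  tot <- 0; np <- 0
  for (i in seq_along(idx)) for (j in seq_along(idx)) if (i != j) {
    tot <- tot + d[i, j]; np <- np + 1
  }
  tot / np
}

oracle_largest_component_fraction <- function(a) {
  max(tabulate(oracle_components(a))) / nrow(a)
}

oracle_assortativity <- function(a) {
  n <- nrow(a)
  deg <- rowSums(a)
  js <- c(); ks <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j && a[i, j] > 0) {
    js <- c(js, deg[i]); ks <- c(ks, deg[j])
  }
  e <- length(js)
  if (e == 0) stop("edgeless")
  t1 <- sum(js * ks) / e
  t2 <- (sum((js + ks) / 2) / e)^2
  t3 <- sum((js^2 + ks^2) / 2) / e
  if (abs(t3 - t2) < 1e-12) return(NA_real_)
  (t1 - t2) / (t3 - t2)
}

oracle_global_efficiency <- function(a) {
  n <- nrow(a)
  d <- oracle_floyd_warshall(a)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    tot <- tot + 1 / d[i, j]
  tot / (n * (n - 1))
}

oracle_local_efficiency <- function(a) {
  n <- nrow(a)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    vals[i] <- if (length(nb) < 2) 0
               else oracle_global_efficiency(a[nb, nb, drop = FALSE])
  }
  mean(vals)
}

oracle_rich_club <- function(a, k) {
  deg <- rowSums(a)
  rich <- which(deg >= k)
  if (length(rich) < 2) return(NA_real_)
  e <- 0
  for (i in rich) for (j in rich) if (i < j && a[i, j] > 0) e <- e + 1
  2 * e / (length(rich) * (length(rich) - 1))
}

# --- random fixtures ------------------------------------------------------

random_adjacency <- function(n, p) {
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- as.numeric(runif(sum(ut)) < p)
  a + t(a)
}

random_weight_matrix <- function(n, p = 0.5, max_w = 100) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- ifelse(runif(sum(ut)) < p, sample.int(max_w, sum(ut), replace = TRUE), 0)
  w[ut] <- vals
  w + t(w)
}

# adjacency matrix builders for named small graphs
adj_from_edges <- function(n, edges) {
  a <- matrix(0, n, n)
  for (e in edges) { a[e[1], e[2]] <- 1; a[e[2], e[1]] <- 1 }
  a
}

complete_adj <- function(n) {
  a <- matrix(1, n, n); diag(a) <- 0; a
}

path_adj <- function(n) adj_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))

star_adj <- function(n_leaves) adj_from_edges(n_leaves + 1,
  lapply(seq_len(n_leaves), function(i) c(1, i + 1)))
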
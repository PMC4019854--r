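# Internal helpers shared across modules.

# round() in R rounds half to even; edge budgets need deterministic half-up.
round_half_up <- function(x) floor(x + 0.5)

# Default region labels when a matrix file or config carries none.
default_node_labels <- function(n) sprintf("region_%04d", seq_len(n))

# Upper-triangle (i < j) index pairs of an N x N matrix, in row-major
# (i ascending, then j ascending) order. This is the index order used for
# deterministic tie-breaking during thresholding.
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

# Trapezoid-rule weights for a strictly increasing grid: sum(w * y) equals
# the trapezoidal integral of y over the grid.
trapezoid_weights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("trapezoid rule needs at least 2 grid points", call. = FALSE)
  dx <- diff(x)
  w <- numeric(n)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

# Seed arithmetic for deriving independent streams; keeps results inside the
# 32-bit integer range set.seed() accepts.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + as.double(offset)) %% 2147483647)
}

# Evaluate `expr` with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
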
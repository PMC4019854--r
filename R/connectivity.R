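#' Construct a connectivity matrix
#'
#' A `connectivity_matrix` holds one subject/session/group observation of a
#' structural brain network: a square, symmetric, nonnegative matrix whose
#' entry (i, j) counts the tractography streamlines connecting regions i and
#' j. The diagonal is zero (streamlines must connect two distinct regions).
#'
#' @param weights Square numeric matrix of nonnegative streamline counts;
#'   symmetric with zero diagonal.
#' @param node_labels Optional character vector of region names, one per node;
#'   defaults to `region_0001`, `region_0002`, ...
#' @param subject_id,session_id,group Identity of the observation within a
#'   test-retest cohort. `group` typically names the tracking algorithm or
#'   any other grouping under comparison.
#' @param validate If `TRUE` (default) the invariants are checked via
#'   [validate_matrix()].
#'
#' @return An object of class `connectivity_matrix`: a list with elements
#'   `weights`, `node_labels`, `subject_id`, `session_id`, `group`.
#' @seealso [validate_matrix()], [max_density()], [threshold_to_density()]
#' @export
#' @examples
#' w <- matrix(0, 3, 3)
#' w[1, 2] <- w[2, 1] <- 12
#' w[2, 3] <- w[3, 2] <- 4
#' m <- connectivity_matrix(w, subject_id = "sub01", session_id = "ses1")
#' max_density(m)
connectivity_matrix <- function(weights, node_labels = NULL,
                                subject_id = NA_character_,
                                session_id = NA_character_,
                                group = NA_character_,
                                validate = TRUE) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (is.null(node_labels)) {
    node_labels <- if (!is.null(rownames(weights))) rownames(weights)
                   else default_node_labels(nrow(weights))
  }
  node_labels <- as.character(node_labels)
  if (nrow(weights) == ncol(weights) && length(node_labels) == nrow(weights))
    dimnames(weights) <- list(node_labels, node_labels)
  m <- structure(
    list(weights = weights, node_labels = node_labels,
         subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         group = as.character(group)),
    class = "connectivity_matrix"
  )
  if (validate) validate_matrix(m) else m
}

#' Validate connectivity-matrix invariants
#'
#' Checks that the weight matrix is square with at least two nodes, numeric
#' and finite, nonnegative, symmetric, and has a zero diagonal. Each violated
#' invariant raises its own error message.
#'
#' @param m A [connectivity_matrix()].
#' @return `m`, unchanged, if all invariants hold.
#' @export
validate_matrix <- function(m) {
  if (!inherits(m, "connectivity_matrix"))
    stop("not a connectivity_matrix object", call. = FALSE)
  w <- m$weights
  if (!is.matrix(w) || !is.numeric(w))
    stop("weights must be a numeric matrix", call. = FALSE)
  if (nrow(w) != ncol(w))
    stop(sprintf("weights must be square (got %d x %d)", nrow(w), ncol(w)),
         call. = FALSE)
  if (nrow(w) < 2L)
    stop("connectivity matrix needs at least 2 nodes", call. = FALSE)
  if (anyNA(w) || any(!is.finite(w)))
    stop("weights contain missing or non-finite entries", call. = FALSE)
  if (any(w < 0))
    stop("negative entry in connectivity matrix", call. = FALSE)
  if (any(w != t(w)))
    stop("connectivity matrix is asymmetric", call. = FALSE)
  if (any(diag(w) != 0))
    stop("nonzero diagonal in connectivity matrix (self-connections not allowed)",
         call. = FALSE)
  if (length(m$node_labels) != nrow(w))
    stop("node_labels length does not match matrix dimension", call. = FALSE)
  m
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf(
    "<connectivity_matrix> %d nodes | subject=%s session=%s group=%s | max density %.4f\n",
    nrow(x$weights), x$subject_id, x$session_id, x$group, max_density(x)))
  invisible(x)
}

#' Maximum achievable graph density of a connectivity matrix
#'
#' The density of the binary graph containing every strictly positive edge of
#' the matrix, i.e. the largest density at which the matrix can be
#' thresholded. Density uses the ordered-pair convention 2E / (N (N - 1)) so
#' that it spans \[0, 1\] (see [compute_density()]).
#'
#' @param m A [connectivity_matrix()].
#' @return Real in \[0, 1\].
#' @export
max_density <- function(m) {
  w <- m$weights
  n <- nrow(w)
  e <- sum(w[upper.tri(w)] > 0)
  2 * e / (n * (n - 1))
}
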
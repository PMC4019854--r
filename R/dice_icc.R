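# Topological similarity (edge-wise Dice) and test-retest reliability (ICC)
# as functions of the curve parameter.

#' Edge-wise Dice coefficient of two binary graphs
#'
#' `Dice(a, b) = 2 |E(a) ∩ E(b)| / (|E(a)| + |E(b)|)`, where edges are
#' equal when they join the same two nodes. Equivalent to Dice overlap of the
#' binarized adjacency matrices viewed as 2D images. Two empty edge sets are
#' identical topologies and score 1.
#'
#' @param a,b [binary_graph()] objects over the same node set, in the same
#'   order.
#' @return Real in \[0, 1\].
#' @export
edge_dice <- function(a, b) {
  if (!identical(a$node_labels, b$node_labels))
    stop("graphs have mismatched node sets", call. = FALSE)
  ua <- a$adjacency[upper.tri(a$adjacency)] > 0
  ub <- b$adjacency[upper.tri(b$adjacency)] > 0
  ea <- sum(ua); eb <- sum(ub)
  if (ea + eb == 0L) return(1)
  2 * sum(ua & ub) / (ea + eb)
}

#' Intra- and inter-subject Dice similarity over a density grid
#'
#' For a single-group test-retest cohort (every subject measured in exactly
#' two sessions), thresholds every matrix at each grid density and computes
#' the mean edge-Dice over each subject's session pair (intra) and over all
#' cross-subject graph pairs, all four session combinations per subject pair
#' (inter).
#'
#' @param dataset List of [connectivity_matrix()] objects from one group,
#'   >= 2 subjects x exactly 2 sessions.
#' @param grid A density [parameter_grid()].
#' @return An object of class `dice_summary`: list with `grid`, `intra_mean`
#'   and `inter_mean` (numeric per grid point), and `pairs`, a long
#'   `data.frame` of every pairwise Dice value (columns `parameter`, `type`,
#'   `subject_a`, `session_a`, `subject_b`, `session_b`, `dice`) retained for
#'   permutation use.
#' @export
dice_curves <- function(dataset, grid) {
  if (!inherits(grid, "parameter_grid") || grid$kind != "density")
    stop("grid must be a density parameter_grid", call. = FALSE)
  groups <- unique(vapply(dataset, function(m) m$group, character(1)))
  if (length(groups) > 1L)
    stop("dice_curves expects matrices from a single group", call. = FALSE)
  subj <- vapply(dataset, function(m) m$subject_id, character(1))
  sess <- vapply(dataset, function(m) m$session_id, character(1))
  per_subj <- table(subj)
  if (length(per_subj) < 2L)
    stop("dice_curves needs at least 2 subjects", call. = FALSE)
  if (any(per_subj != 2L))
    stop(sprintf("every subject needs exactly 2 sessions (violated by: %s)",
                 paste(names(per_subj)[per_subj != 2L], collapse = ", ")),
         call. = FALSE)
  n <- length(dataset)
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pair_type <- ifelse(subj[pair_idx[, 1]] == subj[pair_idx[, 2]],
                      "intra", "inter")
  rows <- vector("list", length(grid$values))
  for (gi in seq_along(grid$values)) {
    d <- grid$values[gi]
    graphs <- lapply(dataset, threshold_to_density, target_density = d)
    dice <- vapply(seq_len(nrow(pair_idx)), function(p) {
      edge_dice(graphs[[pair_idx[p, 1]]], graphs[[pair_idx[p, 2]]])
    }, numeric(1))
    rows[[gi]] <- data.frame(
      parameter = d, type = pair_type,
      subject_a = subj[pair_idx[, 1]], session_a = sess[pair_idx[, 1]],
      subject_b = subj[pair_idx[, 2]], session_b = sess[pair_idx[, 2]],
      dice = dice, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  intra <- vapply(grid$values, function(d)
    mean(pairs$dice[pairs$parameter == d & pairs$type == "intra"]), numeric(1))
  inter <- vapply(grid$values, function(d)
    mean(pairs$dice[pairs$parameter == d & pairs$type == "inter"]), numeric(1))
  structure(list(grid = grid, intra_mean = intra, inter_mean = inter,
                 pairs = pairs),
            class = "dice_summary")
}

#' @export
print.dice_summary <- function(x, ...) {
  cat(sprintf(
    "<dice_summary> %d densities | mean intra %.3f | mean inter %.3f\n",
    length(x$grid$values), mean(x$intra_mean), mean(x$inter_mean)))
  invisible(x)
}

#' Tidy table of a Dice summary
#'
#' @param x A `dice_summary` from [dice_curves()].
#' @return `data.frame` with columns `parameter`, `intra_mean`, `inter_mean`.
#' @export
dice_to_table <- function(x) {
  data.frame(parameter = x$grid$values, intra_mean = x$intra_mean,
             inter_mean = x$inter_mean)
}

#' One-way random-effects intraclass correlation coefficient
#'
#' Method-of-moments estimator from the one-way random-effects ANOVA
#' decomposition of a balanced subject x session table:
#' `ICC = sigma2_bs / (sigma2_bs + sigma2_ws)` with
#' `sigma2_ws = MSW` (within-subject mean square) and
#' `sigma2_bs = max(0, (MSB - MSW) / k)` for k sessions. When the metric
#' carries little to no variance (`MSB + MSW < tol`) the ICC becomes unstable
#' and is flagged invalid rather than reported.
#'
#' @param values Numeric matrix (or data.frame) of observations, one row per
#'   subject, one column per session; must be balanced and complete.
#' @param tol Total-mean-square threshold below which the ICC is not
#'   calculated (default `1e-10`).
#' @return List with `icc` (clamped, in \[0, 1\]; `NA` when invalid),
#'   `valid`, `n_subjects`, `n_sessions`, and the variance components
#'   `sigma2_between`, `sigma2_within`, plus `sigma2_between_unclamped` for
#'   transparency.
#' @export
icc_oneway <- function(values, tol = 1e-10) {
  values <- as.matrix(values)
  if (anyNA(values))
    stop("icc_oneway requires a complete (balanced) table", call. = FALSE)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L) stop("icc_oneway needs at least 2 subjects", call. = FALSE)
  if (k < 2L) stop("icc_oneway needs at least 2 sessions", call. = FALSE)
  subj_means <- rowMeans(values)
  grand <- mean(values)
  msb <- k * sum((subj_means - grand)^2) / (n - 1)
  msw <- sum((values - subj_means)^2) / (n * (k - 1))
  if (msb + msw < tol) {
    return(list(icc = NA_real_, valid = FALSE,
                n_subjects = n, n_sessions = k,
                sigma2_between = NA_real_, sigma2_within = msw,
                sigma2_between_unclamped = NA_real_))
  }
  s2b_raw <- (msb - msw) / k
  s2b <- max(0, s2b_raw)
  list(icc = s2b / (s2b + msw), valid = TRUE,
       n_subjects = n, n_sessions = k,
       sigma2_between = s2b, sigma2_within = msw,
       sigma2_between_unclamped = s2b_raw)
}

#' ICC reproducibility curve from a cohort of graph curves
#'
#' At each grid point, assembles the subject x session table of metric values
#' and applies [icc_oneway()]. Points where any curve is undefined, or where
#' the total variance falls below the instability threshold, are flagged
#' invalid and carry no ICC.
#'
#' @param curves List of [graph_curve()] objects, exactly one per
#'   subject x session, sharing one grid, metric and group.
#' @param tol Passed to [icc_oneway()].
#' @return An object of class `icc_result`: list with `grid`, `icc` (numeric
#'   per point, `NA` where invalid), `valid` (logical per point),
#'   `n_subjects`, `n_sessions`, `metric_name`, `group`.
#' @export
icc_curve <- function(curves, tol = 1e-10) {
  if (length(curves) < 4L)
    stop("icc_curve needs curves for at least 2 subjects x 2 sessions",
         call. = FALSE)
  grid <- curves[[1]]$grid
  for (cv in curves)
    if (!identical(cv$grid$values, grid$values) ||
        !identical(cv$grid$kind, grid$kind))
      stop("curves have mismatched grids", call. = FALSE)
  subj <- vapply(curves, function(cv) cv$subject_id, character(1))
  sess <- vapply(curves, function(cv) cv$session_id, character(1))
  subjects <- sort(unique(subj))
  sessions <- sort(unique(sess))
  per <- table(subj)
  if (any(per != length(sessions)))
    stop("unbalanced cohort: each subject needs one curve per session",
         call. = FALSE)
  # values[subject, session, grid point]
  vals <- array(NA_real_,
                c(length(subjects), length(sessions), length(grid$values)))
  for (ci in seq_along(curves)) {
    vals[match(subj[ci], subjects), match(sess[ci], sessions), ] <-
      curves[[ci]]$values
  }
  icc <- rep(NA_real_, length(grid$values))
  valid <- rep(FALSE, length(grid$values))
  for (gi in seq_along(grid$values)) {
    tab <- vals[, , gi]
    if (anyNA(tab)) next
    res <- icc_oneway(tab, tol = tol)
    icc[gi] <- res$icc
    valid[gi] <- res$valid
  }
  structure(list(grid = grid, icc = icc, valid = valid,
                 n_subjects = length(subjects),
                 n_sessions = length(sessions),
                 metric_name = curves[[1]]$metric_name,
                 group = curves[[1]]$group),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "<icc_result> %s [%s]: %d points, %d valid, median ICC %.3f\n",
    x$metric_name, x$group, length(x$icc), sum(x$valid),
    stats::median(x$icc[x$valid])))
  invisible(x)
}

#' Qualitative agreement category of an ICC value
#'
#' Standard interpretation guidelines: below 0.2 "poor"; 0.2-0.40 "fair";
#' 0.41-0.60 "moderate"; 0.61-0.80 "strong"; above 0.8 "near-perfect". The
#' printed guideline list leaves (0.2, 0.21) unassigned; values there are
#' assigned to "fair" (the category boundaries used are `< 0.2`, `<= 0.40`,
#' `<= 0.60`, `<= 0.80`, `> 0.8`).
#'
#' @param icc Numeric vector of ICC values.
#' @return Character vector of categories.
#' @export
icc_category <- function(icc) {
  vapply(icc, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 0.2) "poor"
    else if (x <= 0.40) "fair"
    else if (x <= 0.60) "moderate"
    else if (x <= 0.80) "strong"
    else "near-perfect"
  }, character(1))
}

#' Tidy table of an ICC result
#'
#' @param x An `icc_result` from [icc_curve()].
#' @return `data.frame` with columns `group`, `metric`, `parameter`, `icc`,
#'   `valid`, `category`.
#' @export
icc_to_table <- function(x) {
  data.frame(group = x$group, metric = x$metric_name,
             parameter = x$grid$values, icc = x$icc, valid = x$valid,
             category = icc_category(x$icc), stringsAsFactors = FALSE)
}
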
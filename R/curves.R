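#' Parameter grid for graph curves
#'
#' The shared x-axis on which graph curves are sampled: either graph
#' densities (reals in (0, 1\]) or rich-club degree levels k (nonnegative
#' integers).
#'
#' @param kind `"density"` or `"degree_k"`.
#' @param values Nonempty, strictly increasing numeric vector; densities must
#'   lie in (0, 1\], degree levels must be nonnegative integers.
#' @return An object of class `parameter_grid`.
#' @export
parameter_grid <- function(kind = c("density", "degree_k"), values) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) == 0L)
    stop("parameter grid must be nonempty", call. = FALSE)
  if (anyNA(values) || any(diff(values) <= 0))
    stop("parameter grid values must be strictly increasing", call. = FALSE)
  if (kind == "density" && (any(values <= 0) || any(values > 1)))
    stop("density grid values must lie in (0, 1]", call. = FALSE)
  if (kind == "degree_k" && (any(values < 0) || any(values != floor(values))))
    stop("degree_k grid values must be nonnegative integers", call. = FALSE)
  structure(list(kind = kind, values = values), class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("<parameter_grid> %s: %d points in [%g, %g]\n",
              x$kind, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Graph curve: a metric sampled along a parameter grid
#'
#' @param grid A [parameter_grid()].
#' @param values Numeric vector aligned with `grid$values`; `NA` marks points
#'   where the metric is undefined.
#' @param metric_name Name of the sampled metric.
#' @param subject_id,session_id,group Identity of the underlying observation.
#' @return An object of class `graph_curve`.
#' @export
graph_curve <- function(grid, values, metric_name,
                        subject_id = NA_character_,
                        session_id = NA_character_,
                        group = NA_character_) {
  if (!inherits(grid, "parameter_grid"))
    stop("grid must be a parameter_grid", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) != length(grid$values))
    stop("curve values must align with the grid", call. = FALSE)
  structure(
    list(grid = grid, values = values, metric_name = as.character(metric_name),
         subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         group = as.character(group)),
    class = "graph_curve")
}

#' @export
print.graph_curve <- function(x, ...) {
  cat(sprintf("<graph_curve> %s over %s (%d points, %d undefined) [%s/%s/%s]\n",
              x$metric_name, x$grid$kind, length(x$values),
              sum(is.na(x$values)), x$subject_id, x$session_id, x$group))
  invisible(x)
}

#' Highest density range common to a dataset
#'
#' Graphs can only be compared at densities achievable by every matrix, so
#' the grid runs from `step` up to the minimum over the dataset of
#' [max_density()], inclusive, in increments of `step`.
#'
#' @param dataset Nonempty list of [connectivity_matrix()] objects.
#' @param step Grid increment (> 0); default 0.01.
#' @return A density [parameter_grid()].
#' @export
common_density_range <- function(dataset, step = 0.01) {
  if (length(dataset) == 0L)
    stop("dataset is empty", call. = FALSE)
  if (!is.numeric(step) || length(step) != 1L || is.na(step) || step <= 0)
    stop("step must be a single positive number", call. = FALSE)
  dmin <- min(vapply(dataset, max_density, numeric(1)))
  if (dmin < step - 1e-12)
    stop(sprintf(
      "no common density grid: minimum achievable density %.6g is below step %.6g",
      dmin, step), call. = FALSE)
  values <- seq(step, dmin + 1e-12, by = step)
  parameter_grid("density", values)
}

#' Metric-vs-density graph curve for one matrix
#'
#' Thresholds the matrix at each grid density and evaluates the named metric
#' on the resulting binary graph. Undefined points (e.g. assortativity of a
#' regular graph, path length of an edgeless graph) are carried as `NA`, not
#' interpolated.
#'
#' @param m A [connectivity_matrix()].
#' @param metric_name One of `"clustering"`, `"char_path_length"`,
#'   `"largest_component_size"` (reported as fraction of N),
#'   `"assortativity"`, `"global_efficiency"`, `"local_efficiency"`.
#' @param grid A density [parameter_grid()] with all values <=
#'   [max_density()] of `m`.
#' @return A [graph_curve()] carrying the matrix identity.
#' @export
metric_curve <- function(m, metric_name, grid) {
  if (!inherits(grid, "parameter_grid") || grid$kind != "density")
    stop("grid must be a density parameter_grid", call. = FALSE)
  f <- metric_function(metric_name)
  vals <- vapply(grid$values,
                 function(d) f(threshold_to_density(m, d)), numeric(1))
  graph_curve(grid, vals, metric_name, m$subject_id, m$session_id, m$group)
}

#' Rich-club coefficient as a function of degree level k
#'
#' Thresholds the matrix once at a fixed density, then evaluates the
#' rich-club coefficient over a grid of degree levels. Levels exceeded by no
#' node (fewer than two nodes of degree >= k) yield `NA`.
#'
#' @param m A [connectivity_matrix()].
#' @param density Fixed graph density at which to threshold (default 0.15),
#'   or `"common"` inside [run_pipeline()] to use the highest density common
#'   to all graphs.
#' @param k_values A degree-level [parameter_grid()].
#' @return A [graph_curve()] with metric name `"rich_club"`.
#' @export
rich_club_curve <- function(m, density = 0.15, k_values) {
  if (!inherits(k_values, "parameter_grid") || k_values$kind != "degree_k")
    stop("k_values must be a degree_k parameter_grid", call. = FALSE)
  g <- threshold_to_density(m, density)
  vals <- vapply(k_values$values,
                 function(k) rich_club_coefficient(g, k), numeric(1))
  graph_curve(k_values, vals, "rich_club", m$subject_id, m$session_id, m$group)
}

#' Tidy long-format table of graph curves
#'
#' @param curves A single [graph_curve()] or a list of them.
#' @return `data.frame` with columns `subject`, `session`, `group`, `metric`,
#'   `parameter`, `value`, `defined`.
#' @export
curves_to_table <- function(curves) {
  if (inherits(curves, "graph_curve")) curves <- list(curves)
  do.call(rbind, lapply(curves, function(cv) {
    data.frame(
      subject = cv$subject_id, session = cv$session_id, group = cv$group,
      metric = cv$metric_name, parameter = cv$grid$values,
      value = cv$values, defined = !is.na(cv$values),
      stringsAsFactors = FALSE)
  }))
}
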
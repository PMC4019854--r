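# End-to-end orchestration: manifest -> common grid -> metric and rich-club
# curves -> Dice summaries -> ICC curves -> pairwise-group permutation tests,
# all written as tidy delimited tables.

#' Run the full reproducibility analysis pipeline
#'
#' Loads a test-retest dataset, finds the highest density range common to
#' all matrices, builds metric-vs-density curves and rich-club-vs-k curves
#' for every matrix, summarizes intra-/inter-subject edge-Dice similarity
#' per group, computes ICC reproducibility curves per group and metric, and
#' runs the permutation test on the area between group mean curves for every
#' pairwise group combination (per metric, for rich-club curves, and for
#' intra-subject Dice curves). All outputs are tidy delimited tables; runs
#' are fully determined by `seed`, so reruns are byte-identical.
#'
#' @param manifest Manifest path, the `data.frame` from [read_manifest()],
#'   or a list of [connectivity_matrix()] objects.
#' @param out_dir Output directory (created if needed).
#' @param density_step Density grid increment (default 0.01).
#' @param rich_club_density Fixed density for rich-club curves (default
#'   0.15), or `"common"` for the highest density common to all graphs.
#' @param rich_club_k_max Largest degree level; default (`NULL`) uses the
#'   maximum degree observed across all graphs thresholded at the rich-club
#'   density.
#' @param metrics Metric names for density curves; defaults to all six.
#' @param n_iterations Permutation count for the group tests (default 10000).
#' @param seed Integer seed controlling the permutation tests.
#' @return Invisibly, a list with elements `grid`, `metric_curves`,
#'   `rich_club_curves`, `dice`, `icc`, `fda` (the tidy tables) and
#'   `out_dir`. Written files: `metric_curves.csv`, `rich_club_curves.csv`,
#'   `dice_curves.csv`, `icc_curves.csv`, `fda_results.csv`, `config.txt`,
#'   `run.log`.
#' @export
run_pipeline <- function(manifest, out_dir,
                         density_step = 0.01,
                         rich_club_density = 0.15,
                         rich_club_k_max = NULL,
                         metrics = metric_names(),
                         n_iterations = 10000,
                         seed = 1) {
  dataset <- if (is.list(manifest) && length(manifest) > 0 &&
                 inherits(manifest[[1]], "connectivity_matrix")) manifest
             else read_dataset(manifest)
  bad <- setdiff(metrics, metric_names())
  if (length(bad) > 0)
    stop(sprintf("unknown metric(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  ids <- data.frame(
    subject = vapply(dataset, function(m) m$subject_id, character(1)),
    session = vapply(dataset, function(m) m$session_id, character(1)),
    group = vapply(dataset, function(m) m$group, character(1)),
    stringsAsFactors = FALSE)
  groups <- sort(unique(ids$group))
  note("dataset: %d matrices, %d group(s): %s", length(dataset),
       length(groups), paste(groups, collapse = ", "))

  grid <- common_density_range(dataset, density_step)
  note("common density grid: step %g, %d points, max %g", density_step,
       length(grid$values), max(grid$values))

  rc_density <- if (identical(rich_club_density, "common"))
    max(grid$values) else rich_club_density
  if (rc_density > max(grid$values) + 1e-12)
    stop(sprintf(
      "rich-club density %.4g exceeds the common maximum %.4g; use rich_club_density = \"common\"",
      rc_density, max(grid$values)), call. = FALSE)

  # metric-vs-density curves for every matrix
  metric_curves <- list()
  for (mi in seq_along(dataset)) {
    for (met in metrics) {
      metric_curves[[length(metric_curves) + 1L]] <-
        metric_curve(dataset[[mi]], met, grid)
    }
  }
  note("metric curves: %d metrics x %d matrices", length(metrics),
       length(dataset))

  # rich-club-vs-k curves at fixed density
  if (is.null(rich_club_k_max)) {
    rich_club_k_max <- max(vapply(dataset, function(m)
      max(degrees(threshold_to_density(m, rc_density))), numeric(1)))
  }
  k_grid <- parameter_grid("degree_k", 0:rich_club_k_max)
  rc_curves <- lapply(dataset, rich_club_curve, density = rc_density,
                      k_values = k_grid)
  note("rich-club curves at density %g, k = 0..%d", rc_density,
       rich_club_k_max)

  pick <- function(curves, keep) curves[keep]
  curve_group <- function(curves)
    vapply(curves, function(cv) cv$group, character(1))
  curve_metric <- function(curves)
    vapply(curves, function(cv) cv$metric_name, character(1))

  # per-group Dice summaries and intra-subject Dice curves (for FDA)
  dice_tables <- list()
  intra_dice_curves <- list()
  for (g in groups) {
    ds <- dice_curves(dataset[ids$group == g], grid)
    tab <- dice_to_table(ds)
    tab <- cbind(group = g, tab, stringsAsFactors = FALSE)
    dice_tables[[g]] <- tab
    intra <- ds$pairs[ds$pairs$type == "intra", ]
    for (s in unique(intra$subject_a)) {
      sub <- intra[intra$subject_a == s, ]
      sub <- sub[order(sub$parameter), ]
      intra_dice_curves[[length(intra_dice_curves) + 1L]] <-
        graph_curve(grid, sub$dice, "intra_subject_dice",
                    subject_id = s, group = g)
    }
    note("dice summary [%s]: mean intra %.4f, mean inter %.4f", g,
         mean(ds$intra_mean), mean(ds$inter_mean))
  }
  dice_table <- do.call(rbind, dice_tables)

  # per-group, per-metric ICC curves (plus rich-club ICC)
  icc_tables <- list()
  for (g in groups) {
    for (met in metrics) {
      keep <- curve_group(metric_curves) == g & curve_metric(metric_curves) == met
      res <- icc_curve(pick(metric_curves, keep))
      icc_tables[[length(icc_tables) + 1L]] <- icc_to_table(res)
    }
    res <- icc_curve(pick(rc_curves, curve_group(rc_curves) == g))
    icc_tables[[length(icc_tables) + 1L]] <- icc_to_table(res)
  }
  icc_table <- do.call(rbind, icc_tables)
  note("ICC curves: %d group x metric combinations", length(icc_tables))

  # pairwise-group FDA permutation tests
  fda_rows <- list()
  test_id <- 0L
  run_fda <- function(curves, what, g1, g2) {
    keep <- curve_group(curves) %in% c(g1, g2)
    cvs <- pick(curves, keep)
    labs <- curve_group(cvs)
    test_id <<- test_id + 1L
    res <- permutation_test_curves(cvs, labs, n_iterations = n_iterations,
                                   seed = derive_seed(seed, test_id))
    data.frame(comparison = what, group_a = g1, group_b = g2,
               observed_area = res$observed_area, p_value = res$p_value,
               x_count = res$x_count, n_iterations = res$n_iterations,
               n_a = res$group_sizes[1], n_b = res$group_sizes[2],
               stringsAsFactors = FALSE)
  }
  if (length(groups) >= 2) {
    for (a in seq_len(length(groups) - 1)) {
      for (b in seq((a + 1), length(groups))) {
        g1 <- groups[a]; g2 <- groups[b]
        for (met in metrics) {
          keep <- curve_metric(metric_curves) == met
          fda_rows[[length(fda_rows) + 1L]] <-
            run_fda(pick(metric_curves, keep), met, g1, g2)
        }
        fda_rows[[length(fda_rows) + 1L]] <- run_fda(rc_curves, "rich_club",
                                                     g1, g2)
        fda_rows[[length(fda_rows) + 1L]] <-
          run_fda(intra_dice_curves, "intra_subject_dice", g1, g2)
      }
    }
    note("FDA permutation tests: %d comparisons, %d iterations each, seed %d",
         length(fda_rows), n_iterations, seed)
  } else {
    note("FDA permutation tests skipped: single group")
  }
  fda_table <- if (length(fda_rows) > 0) do.call(rbind, fda_rows) else
    data.frame(comparison = character(0), group_a = character(0),
               group_b = character(0), observed_area = numeric(0),
               p_value = numeric(0), x_count = integer(0),
               n_iterations = integer(0), n_a = integer(0), n_b = integer(0))

  metric_table <- curves_to_table(metric_curves)
  rc_table <- curves_to_table(rc_curves)

  wr <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE, quote = FALSE)
  wr(metric_table, "metric_curves.csv")
  wr(rc_table, "rich_club_curves.csv")
  wr(dice_table, "dice_curves.csv")
  wr(icc_table, "icc_curves.csv")
  wr(fda_table, "fda_results.csv")
  writeLines(c(
    sprintf("density_step: %.17g", density_step),
    sprintf("rich_club_density: %.17g", rc_density),
    sprintf("rich_club_k_max: %d", as.integer(rich_club_k_max)),
    sprintf("metrics: %s", paste(metrics, collapse = ",")),
    sprintf("n_iterations: %d", as.integer(n_iterations)),
    sprintf("seed: %d", as.integer(seed))),
    file.path(out_dir, "config.txt"))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(grid = grid, metric_curves = metric_table,
                 rich_club_curves = rc_table, dice = dice_table,
                 icc = icc_table, fda = fda_table, out_dir = out_dir))
}
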
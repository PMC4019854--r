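# Synthetic test-retest connectome cohorts. The generator stands in for
# everything upstream of the connectivity matrix (imaging, registration,
# tractography): it emulates a cohort of S subjects scanned in 2 sessions,
# with one matrix per subject x session x group and controllable
# between-subject / within-session variability and group effects on topology.

#' Configuration for the synthetic test-retest cohort generator
#'
#' The population backbone is a modular random graph: node pairs within a
#' module carry an edge with probability `p_in`, pairs across modules with
#' probability `p_out`, and present edges get an expected streamline count of
#' `weight_scale` times a log-normal(0, 1) draw. Each group re-draws its own
#' backbone with `p_in` scaled by that group's effect, so group effects act
#' on network topology. Subject and session variability act multiplicatively
#' on the expected counts (additively on log-weights), and observed counts
#' are Poisson draws around the subject/session expectation.
#'
#' Defaults emulate a 21-subject, 2-session test-retest cohort on 78 cortical
#' and deep-gray regions, with between-subject variability well above
#' session-to-session variability and two groups carrying no topological
#' group effect.
#'
#' @param n_nodes Number of regions (nodes) per matrix.
#' @param n_subjects Number of subjects (>= 2).
#' @param n_sessions Sessions per subject (>= 2).
#' @param groups Named numeric vector: one entry per group, the value being
#'   that group's multiplier on `p_in` (1 = no effect).
#' @param n_modules Number of modules in the population backbone.
#' @param p_in,p_out Within-/between-module edge probabilities of the
#'   backbone; requires `p_in > p_out > 0`.
#' @param weight_scale Mean streamline count on backbone edges (> 0).
#' @param sigma_between Standard deviation of the per-subject, per-edge
#'   log-weight effect (>= 0).
#' @param sigma_within Standard deviation of the per-session, per-edge
#'   log-weight effect (>= 0).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_nodes = 78, n_subjects = 21, n_sessions = 2,
                             groups = c(groupA = 1.0, groupB = 1.0),
                             n_modules = 6, p_in = 0.8, p_out = 0.15,
                             weight_scale = 50,
                             sigma_between = 0.5, sigma_within = 0.1,
                             seed = 1) {
  if (n_nodes < 2) stop("n_nodes must be >= 2", call. = FALSE)
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (n_sessions < 2) stop("n_sessions must be >= 2", call. = FALSE)
  if (length(groups) < 1 || is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named numeric vector of p_in multipliers",
         call. = FALSE)
  if (any(groups <= 0)) stop("group effects must be positive", call. = FALSE)
  if (n_modules > n_nodes)
    stop("infeasible module partition: n_modules exceeds n_nodes",
         call. = FALSE)
  if (!(p_in > p_out && p_out > 0))
    stop("need p_in > p_out > 0", call. = FALSE)
  if (weight_scale <= 0) stop("weight_scale must be > 0", call. = FALSE)
  if (sigma_between < 0 || sigma_within < 0)
    stop("variance components must be >= 0", call. = FALSE)
  structure(
    list(n_nodes = as.integer(n_nodes), n_subjects = as.integer(n_subjects),
         n_sessions = as.integer(n_sessions), groups = groups,
         n_modules = as.integer(n_modules), p_in = p_in, p_out = p_out,
         weight_scale = weight_scale, sigma_between = sigma_between,
         sigma_within = sigma_within, seed = as.integer(seed)),
    class = "synthetic_config")
}

# Contiguous near-equal module assignment of the nodes.
module_assignment <- function(n_nodes, n_modules) {
  sort(rep_len(seq_len(n_modules), n_nodes))
}

#' Population backbone of expected streamline counts
#'
#' Draws the modular expected-weight template for one group: an edge is
#' present within modules with probability `min(1, p_in * effect)`, between
#' modules with probability `p_out`, and each present edge carries an
#' expected weight `weight_scale * u` with `u ~ log-normal(0, 1)`.
#' Deterministic given the configuration seed and group.
#'
#' @param config A [synthetic_config()].
#' @param group Group name (must match `names(config$groups)`) or index;
#'   defaults to the first group.
#' @return A [connectivity_matrix()] of expected weights, with `group` set
#'   and subject/session unset.
#' @export
generate_base_connectome <- function(config, group = 1L) {
  if (!inherits(config, "synthetic_config"))
    stop("config must be a synthetic_config", call. = FALSE)
  gi <- if (is.character(group)) match(group, names(config$groups)) else
    as.integer(group)
  if (is.na(gi) || gi < 1L || gi > length(config$groups))
    stop("unknown group", call. = FALSE)
  n <- config$n_nodes
  mod <- module_assignment(n, config$n_modules)
  pairs <- upper_pairs(n)
  within <- mod[pairs[, 1]] == mod[pairs[, 2]]
  p_edge <- ifelse(within, min(1, config$p_in * config$groups[[gi]]),
                   config$p_out)
  w <- with_seed(derive_seed(config$seed, 100 + gi), {
    present <- stats::runif(nrow(pairs)) < p_edge
    ifelse(present, config$weight_scale * stats::rlnorm(nrow(pairs), 0, 1), 0)
  })
  wm <- matrix(0, n, n)
  wm[pairs] <- w
  wm[pairs[, c(2, 1)]] <- w
  connectivity_matrix(wm, group = names(config$groups)[gi])
}

#' Generate a synthetic test-retest cohort of connectivity matrices
#'
#' For each group, draws the group backbone ([generate_base_connectome()]);
#' then for each subject a per-edge effect `b_s ~ N(0, sigma_between^2)` and
#' for each session a per-edge effect `e_st ~ N(0, sigma_within^2)`, both on
#' the log-weight scale. The observed count on a backbone edge with expected
#' weight `lambda` is `Poisson(exp(log lambda + b + e))`; in deterministic
#' mode the Poisson draw is replaced by its mean, so `sigma_within = 0`
#' yields identical sessions within each subject.
#'
#' @param config A [synthetic_config()].
#' @param deterministic If `TRUE`, emit expected counts instead of Poisson
#'   draws (for exact-invariant testing).
#' @return List of [connectivity_matrix()] objects, one per
#'   subject x session x group, with `subject_id` (`sub01`, ...),
#'   `session_id` (`ses1`, ...) and `group` set.
#' @export
generate_testretest_dataset <- function(config, deterministic = FALSE) {
  if (!inherits(config, "synthetic_config"))
    stop("config must be a synthetic_config", call. = FALSE)
  out <- list()
  n <- config$n_nodes
  pairs <- upper_pairs(n)
  for (gi in seq_along(config$groups)) {
    base <- generate_base_connectome(config, gi)
    lam <- base$weights[pairs]
    on_edge <- lam > 0
    loglam <- log(lam[on_edge])
    ne <- sum(on_edge)
    mats <- with_seed(derive_seed(config$seed, 7919 + 1000 * gi), {
      res <- list()
      for (s in seq_len(config$n_subjects)) {
        b <- stats::rnorm(ne, 0, config$sigma_between)
        for (t in seq_len(config$n_sessions)) {
          e <- stats::rnorm(ne, 0, config$sigma_within)
          mu <- exp(loglam + b + e)
          counts <- if (deterministic) mu else stats::rpois(ne, mu)
          w <- numeric(nrow(pairs))
          w[on_edge] <- counts
          wm <- matrix(0, n, n)
          wm[pairs] <- w
          wm[pairs[, c(2, 1)]] <- w
          res[[length(res) + 1L]] <- connectivity_matrix(
            wm, base$node_labels,
            subject_id = sprintf("sub%02d", s),
            session_id = sprintf("ses%d", t),
            group = names(config$groups)[gi])
        }
      }
      res
    })
    out <- c(out, mats)
  }
  out
}

#' Gaussian repeated-measures table with known true ICC
#'
#' Generates `value[s, t] = b_s + e_st` with `b ~ N(0, sigma_between^2)` and
#' `e ~ N(0, sigma_within^2)`, so the true intraclass correlation is
#' `sigma_between^2 / (sigma_between^2 + sigma_within^2)` by construction.
#' Used to exercise [icc_oneway()] against known truth.
#'
#' @param n_subjects,n_sessions Table dimensions (both >= 2).
#' @param sigma_between,sigma_within Standard deviations (>= 0).
#' @param seed Integer seed.
#' @return Numeric matrix, subjects in rows, sessions in columns.
#' @export
generate_gaussian_repeated_measures <- function(n_subjects, n_sessions,
                                                sigma_between, sigma_within,
                                                seed = 1) {
  if (n_subjects < 2 || n_sessions < 2)
    stop("need at least 2 subjects and 2 sessions", call. = FALSE)
  with_seed(seed, {
    b <- stats::rnorm(n_subjects, 0, sigma_between)
    e <- matrix(stats::rnorm(n_subjects * n_sessions, 0, sigma_within),
                n_subjects, n_sessions)
    b + e
  })
}
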
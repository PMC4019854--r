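small_config <- function(...) {
  synthetic_config(n_nodes = 24, n_subjects = 4, n_sessions = 2,
                   groups = c(gA = 1.0), n_modules = 3, p_in = 0.8,
                   p_out = 0.15, weight_scale = 30, sigma_between = 0.5,
                   sigma_within = 0.1, seed = 5, ...)
}

test_that("configuration invariants are enforced", {
  expect_s3_class(small_config(), "synthetic_config")
  expect_error(synthetic_config(p_in = 0.1, p_out = 0.2), "p_in > p_out")
  expect_error(synthetic_config(p_out = 0), "p_in > p_out")
  expect_error(synthetic_config(n_subjects = 1), "n_subjects")
  expect_error(synthetic_config(n_sessions = 1), "n_sessions")
  expect_error(synthetic_config(n_modules = 100, n_nodes = 20),
               "infeasible module partition")
  expect_error(synthetic_config(sigma_between = -1), ">= 0")
  expect_error(synthetic_config(groups = c(1, 2)), "named")
})

test_that("base connectome is modular, seeded and block-structured", {
  cfg <- synthetic_config(n_nodes = 20, n_subjects = 2, n_sessions = 2,
                          groups = c(g = 1), n_modules = 2, p_in = 0.9,
                          p_out = 0.2, seed = 3)
  base <- generate_base_connectome(cfg)
  expect_s3_class(validate_matrix(base), "connectivity_matrix")
  base2 <- generate_base_connectome(cfg)
  expect_identical(base$weights, base2$weights)

  # p_out -> 0: block-diagonal expected weights
  cfg0 <- synthetic_config(n_nodes = 20, n_subjects = 2, n_sessions = 2,
                           groups = c(g = 1), n_modules = 2, p_in = 0.9,
                           p_out = 1e-12, seed = 3)
  b0 <- generate_base_connectome(cfg0)
  expect_true(all(b0$weights[1:10, 11:20] == 0))
  expect_gt(sum(b0$weights[1:10, 1:10] > 0), 0)
})

test_that("expected backbone density increases with edge probabilities", {
  mean_density <- function(p_in, p_out) {
    mean(vapply(1:8, function(s) {
      cfg <- synthetic_config(n_nodes = 30, n_subjects = 2, n_sessions = 2,
                              groups = c(g = 1), n_modules = 3, p_in = p_in,
                              p_out = p_out, seed = s)
      max_density(generate_base_connectome(cfg))
    }, numeric(1)))
  }
  expect_gt(mean_density(0.9, 0.3), mean_density(0.5, 0.3))
  expect_gt(mean_density(0.7, 0.4), mean_density(0.7, 0.1))
})

test_that("test-retest datasets satisfy all matrix invariants, deterministically", {
  cfg <- small_config()
  ds <- generate_testretest_dataset(cfg)
  expect_length(ds, 4 * 2)
  for (m in ds) expect_s3_class(validate_matrix(m), "connectivity_matrix")
  expect_true(all(vapply(ds, function(m) all(m$weights == floor(m$weights)),
                         logical(1))))          # Poisson counts are integers
  ds2 <- generate_testretest_dataset(cfg)
  for (i in seq_along(ds))
    expect_identical(ds[[i]]$weights, ds2[[i]]$weights)
  ids <- vapply(ds, function(m) paste(m$subject_id, m$session_id, m$group),
                character(1))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("deterministic mode with zero session noise duplicates sessions exactly", {
  cfg <- synthetic_config(n_nodes = 24, n_subjects = 3, n_sessions = 2,
                          groups = c(g = 1), n_modules = 3, sigma_between = 0.5,
                          sigma_within = 0, seed = 11)
  ds <- generate_testretest_dataset(cfg, deterministic = TRUE)
  subj <- vapply(ds, function(m) m$subject_id, character(1))
  for (s in unique(subj)) {
    pair <- ds[subj == s]
    expect_identical(pair[[1]]$weights, pair[[2]]$weights)
  }
  grid <- common_density_range(ds, 0.05)
  out <- dice_curves(ds, grid)
  expect_true(all(out$intra_mean == 1))
})

test_that("dominant between-subject variance yields intra > inter Dice everywhere", {
  cfg <- synthetic_config(n_nodes = 30, n_subjects = 6, n_sessions = 2,
                          groups = c(g = 1), n_modules = 3,
                          sigma_between = 0.8, sigma_within = 0.05, seed = 23)
  ds <- generate_testretest_dataset(cfg)
  grid <- common_density_range(ds, 0.02)
  out <- dice_curves(ds, grid)
  expect_true(all(out$intra_mean > out$inter_mean))
})

test_that("gaussian repeated measures hit their degenerate ICC values", {
  t1 <- generate_gaussian_repeated_measures(10, 2, 1, 0, seed = 2)
  expect_equal(icc_oneway(t1)$icc, 1.0)
  # with no subject effect the clamped estimator sits at or near 0 (session
  # noise still induces some spurious between-subject mean square)
  t2 <- generate_gaussian_repeated_measures(200, 2, 0, 1, seed = 2)
  expect_gte(icc_oneway(t2)$icc, 0)
  expect_lt(icc_oneway(t2)$icc, 0.15)
  est <- icc_oneway(generate_gaussian_repeated_measures(200, 2, 1, 1, seed = 4))$icc
  expect_lt(abs(est - 0.5), 0.10)
})
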
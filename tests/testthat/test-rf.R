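fast_cfg <- function(seed = 1, ...) rf_config(ntree = 501, seed = seed, ...)

test_that("rf_config enforces its invariants", {
  expect_error(rf_config(ntree = 2000), "odd")
  expect_error(rf_config(drop_fraction = 0), "drop_fraction")
  expect_error(rf_config(drop_fraction = 1), "drop_fraction")
  expect_silent(rf_config())
})

test_that("vote fractions and OOB error are internally consistent", {
  dat <- gauss_data(n = 40, p = 20, n_informative = 5, shift = 2, seed = 2)
  fit <- fit_rf(dat$x, dat$y, fast_cfg(seed = 2))
  expect_true(all(fit$votes >= 0 & fit$votes <= 1))
  recomputed <- mean((fit$votes > 0.5) != (dat$y == "tumor"))
  expect_equal(fit$oob_error, recomputed)
  expect_named(fit$votes, rownames(dat$x))
  expect_error(fit_rf(dat$x[1:3, ], dat$y[1:3], fast_cfg()), ">= 2 samples")
})

test_that("the importance null preserves class sizes and brackets noise", {
  dat <- gauss_data(n = 30, p = 12, n_informative = 0, seed = 3)
  cfg <- rf_config(ntree = 301, seed = 3, n_random_models = 5)
  nul <- importance_null(dat$x, dat$y, cfg)
  expect_equal(dim(nul$null_curves), c(5, 12))
  expect_true(all(apply(nul$null_curves, 1, function(r) all(diff(r) <= 0))))
  expect_true(all(diff(nul$observed) <= 0))
  expect_error(importance_null(dat$x, dat$y,
                               rf_config(n_random_models = 1)), ">= 2")
})

test_that("random-label importance shrinks with more trees", {
  dat <- gauss_data(n = 40, p = 20, n_informative = 0, seed = 4)
  cfg_small <- rf_config(ntree = 501, seed = 4, n_random_models = 10)
  cfg_big <- rf_config(ntree = 2001, seed = 4, n_random_models = 10)
  r1_small <- importance_null(dat$x, dat$y, cfg_small)$null_mean[1]
  r1_big <- importance_null(dat$x, dat$y, cfg_big)$null_mean[1]
  expect_lt(r1_big, r1_small + 0.005)
})

test_that("backward elimination follows the drop schedule and seed contract", {
  expect_equal(biomepair:::backward_sizes(8, 0.5), c(8, 4, 2))
  expect_equal(biomepair:::backward_sizes(112, 0.2)[1:5],
               c(112, 89, 71, 56, 44))
  expect_equal(min(biomepair:::backward_sizes(112, 0.2)), 2)

  dat <- gauss_data(n = 30, p = 10, n_informative = 3, shift = 2, seed = 5)
  cfg <- rf_config(ntree = 301, seed = 5)
  sel <- backward_variable_selection(dat$x, dat$y, cfg)
  # full-feature point of the curve equals the full-model OOB error
  expect_equal(sel$oob_errors[1], fit_rf(dat$x, dat$y, cfg)$oob_error)
  expect_equal(sel$selected_vars,
               sel$ranking[seq_len(sel$selected_size)])
  # ties broken toward the smallest subset
  expect_equal(sel$selected_size,
               min(sel$sizes[sel$oob_errors == min(sel$oob_errors)]))
})

test_that("the no-information rate follows its closed form", {
  expect_equal(no_information_rate(rep(c("a", "b"), 10), rep("a", 20)), 0.5)
  y <- rep(c("a", "b"), 10)
  expect_equal(no_information_rate(y, y), 0.5)  # depends only on marginals
  expect_equal(no_information_rate(rep("a", 5), rep("a", 5)), 0)
  expect_error(no_information_rate(character(0), character(0)), "non-empty")
})

test_that("0.632+ formulas reproduce hand-derived cases", {
  e <- estimate_632plus(0, 0.5, 0.5)
  expect_equal(e$R, 1)
  expect_equal(e$w, 1)
  expect_equal(e$err_632plus, 0.5)

  e2 <- estimate_632plus(0.2, 0.2, 0.5)
  expect_equal(e2$R, 0)
  expect_equal(e2$w, 0.632)
  expect_equal(e2$err_632plus, 0.2)

  set.seed(6)
  for (i in 1:50) {
    v <- runif(3)
    e3 <- estimate_632plus(v[1], v[2], v[3])
    expect_gte(e3$w, 0.632); expect_lte(e3$w, 1)
    expect_gte(e3$err_632plus, min(e3$err_bar, e3$err1_prime) - 1e-12)
    expect_lte(e3$err_632plus, max(e3$err_bar, e3$err1_prime) + 1e-12)
  }
})

test_that("bootstrap evaluation reports selection frequencies and bounds", {
  dat <- gauss_data(n = 16, p = 5, n_informative = 2, shift = 2.5, seed = 7)
  cfg <- rf_config(ntree = 101, seed = 7, n_bootstrap = 40,
                   drop_fraction = 0.5)
  ev <- bootstrap_632plus(dat$x, dat$y, cfg, with_selection = TRUE)
  expect_true(all(c(ev$err_bar, ev$err1, ev$gamma, ev$err_632plus) >= 0))
  expect_true(all(c(ev$err_bar, ev$err1, ev$gamma, ev$err_632plus) <= 1))
  expect_true(all(ev$holdout_counts > 0))
  expect_length(ev$selection_frequency, 5)
  expect_true(all(ev$selection_frequency >= 0 &
                    ev$selection_frequency <= 1))
  expect_equal(sort(unique(ev$error_curves$size)), c(2, 5))
  expect_error(bootstrap_632plus(dat$x, dat$y,
                                 rf_config(ntree = 101, n_bootstrap = 1)),
               "never held out")
})

test_that("vote differences flag direction and exclude voteless pairs", {
  counts_b <- named_mat(rep(c(30, 20), 6), c("g1", "g2"),
                        c("a_T", "a_N", "b_T", "b_N", "c_T", "c_N"))
  counts_f <- named_mat(rep(10, 6), "h1", colnames(counts_b))
  co <- mk_cohort(counts_b, counts_f,
                  t_stage = c(a = "low", b = "high", c = "high"))
  votes <- c(a_T = 1, a_N = 0, b_T = 0.9, b_N = 0.1, c_T = 0.2, c_N = 0.6)
  vd <- vote_fraction_differences(fake_rf_fit(votes), co)
  expect_equal(vd$d, c(1, 0.8, -0.4))
  expect_true(all(vd$correct_direction[1:2]) && !vd$correct_direction[3])
  expect_equal(vd$tumor_correct, c(TRUE, TRUE, FALSE))

  swapped <- votes[c("a_N", "a_T", "b_N", "b_T", "c_N", "c_T")]
  names(swapped) <- names(votes)
  vd2 <- vote_fraction_differences(fake_rf_fit(swapped), co)
  expect_equal(vd2$d, -vd$d)

  expect_message(vd3 <- vote_fraction_differences(
    fake_rf_fit(votes[1:4]), co), "without votes")
  expect_equal(nrow(vd3), 2)
})

test_that("field-effect test compares per-patient d across groups", {
  vd <- data.frame(patient_id = sprintf("p%02d", 1:12),
                   d = c(rnorm(6, 0.3, 0.01), rnorm(6, 0.05, 0.01)),
                   t_stage = rep(c("low", "high"), each = 6))
  class(vd) <- c("vote_diff", class(vd))
  ft <- field_effect_test(vd)
  expect_equal(ft$direction, "high")
  expect_lt(ft$p_value, 0.01)
  expect_equal(unname(ft$means[["low"]]), mean(vd$d[1:6]))

  # identical d multisets in both groups
  same <- vd
  same$t_stage <- rep(c("low", "high"), each = 6)
  same$d <- rep(c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3), 2)
  ftw <- field_effect_test(same, method = "ranksum")
  expect_gt(ftw$p_value, 0.9)

  const <- vd; const$d <- 0.2
  expect_equal(field_effect_test(const)$p_value, 1)
  expect_error(field_effect_test(vd[1:7, ], grouping = "t_stage"),
               ">= 2 patients")
})
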
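small_cv <- function(...) {
  cv_config(nrounds = 30, params = list(max_depth = 3, eta = 0.2,
                                        subsample = 0.9,
                                        colsample_bytree = 0.9), ...)
}

test_that("repeated stratified CV partitions the cohort per repeat", {
  co <- fixture_cohort(400, seed = 3)
  C <- combine_cost(build_rc(), build_hc(class_frequencies(co)), 0.975)
  cfg <- small_cv(n_folds = 5, n_repeats = 2, seed = 17)
  runs <- run_cv(co, C, cfg)
  expect_length(runs, 10)
  y <- derive_labels(co)
  for (r in 1:2) {
    idx <- sort(unlist(lapply(runs[((r - 1) * 5 + 1):(r * 5)],
                              `[[`, "test_idx")))
    expect_identical(idx, seq_len(nrow(co)))
  }
  # stratification: per-fold class counts within 1 of proportional share
  for (run in runs) {
    held <- y[run$test_idx]
    for (k in 0:2) {
      expected_k <- sum(y == k) / 5
      expect_lte(abs(sum(held == k) - expected_k), 1)
    }
  }
  expect_true(all(vapply(runs, function(r) {
    all(abs(rowSums(r$prob) - 1) < 1e-9)
  }, logical(1))))
})

test_that("two-fold single-repeat CV covers a small cohort exactly once", {
  co <- fixture_cohort(40, seed = 12)
  C <- combine_cost(build_rc(), build_hc(c(0.6, 0.25, 0.15)), 0)
  runs <- run_cv(co, C, small_cv(n_folds = 2, n_repeats = 1, seed = 1))
  expect_length(runs, 2)
  expect_identical(sort(c(runs[[1]]$test_idx, runs[[2]]$test_idx)),
                   seq_len(40L))
})

test_that("cross-validation is deterministic given the seed", {
  co <- fixture_cohort(300, seed = 5)
  C <- combine_cost(build_rc(), build_hc(class_frequencies(co)), 0.5)
  cfg <- small_cv(n_folds = 3, n_repeats = 1, seed = 99)
  a <- run_cv(co, C, cfg)
  b <- run_cv(co, C, cfg)
  expect_identical(lapply(a, `[[`, "test_idx"), lapply(b, `[[`, "test_idx"))
  expect_equal(lapply(a, `[[`, "prob"), lapply(b, `[[`, "prob"),
               tolerance = 1e-12)
})

test_that("CV refuses cohorts that cannot be stratified", {
  co <- fixture_cohort(40, seed = 12)
  df <- as.data.frame(co)
  # strip ICU patients down to fewer than n_folds
  icu_rows <- which(derive_labels(df) == 2L)
  keep <- setdiff(seq_len(nrow(df)), icu_rows[-1])
  if (length(icu_rows) < 2) skip("fixture lacks ICU rows to thin")
  df <- df[keep, ]
  C <- combine_cost(build_rc(), build_hc(c(0.6, 0.25, 0.15)), 0)
  expect_error(run_cv(as_cohort(df), C, small_cv(n_folds = 5, n_repeats = 1)),
               "stratification")
})

test_that("external evaluation summarizes metrics across CV models", {
  co <- fixture_cohort(300, seed = 5)
  ext <- fixture_cohort(150, seed = 31)
  C <- combine_cost(build_rc(), build_hc(class_frequencies(co)), 0.975)
  runs <- run_cv(co, C, small_cv(n_folds = 3, n_repeats = 1, seed = 2),
                 keep_models = TRUE)
  res <- evaluate_external(runs, ext)
  expect_equal(nrow(res$per_model), 3)
  expect_true(all(is.finite(res$per_model$auc_mu)))
  expect_true(all(res$summary$ci_lower <= res$summary$mean &
                    res$summary$mean <= res$summary$ci_upper))
  # identical models give zero-width intervals
  runs_same <- rep(runs[1], 4)
  res_same <- evaluate_external(runs_same, ext)
  expect_equal(res_same$summary$sd, rep(0, nrow(res_same$summary)),
               tolerance = 1e-12)
  expect_equal(res_same$summary$ci_upper - res_same$summary$ci_lower,
               rep(0, nrow(res_same$summary)), tolerance = 1e-12)
  expect_error(evaluate_external(run_cv(co, C, small_cv(n_folds = 2,
                                                        n_repeats = 1)),
                                 ext), "keep_models")
})

test_that("hyperparameter search is seeded and improves with budget", {
  co <- fixture_cohort(200, seed = 8)
  C <- combine_cost(build_rc(), build_hc(class_frequencies(co)), 0.975)
  a <- tune_hyperparameters(co, C, budget = 3, seed = 4,
                            nrounds_range = c(10L, 30L))
  b <- tune_hyperparameters(co, C, budget = 3, seed = 4,
                            nrounds_range = c(10L, 30L))
  expect_identical(a$params, b$params)
  one <- tune_hyperparameters(co, C, budget = 1, seed = 4,
                              nrounds_range = c(10L, 30L))
  expect_lte(a$score, one$score)  # best-so-far is monotone in the budget
  expect_equal(one$score, a$trace$score[1])
  expect_warning(res <- tune_hyperparameters(co, C, budget = 0), "default")
  expect_identical(res$nrounds, cv_config()$nrounds)
})
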
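#' Cross-validation configuration
#'
#' Defaults follow the study design: stratified fivefold cross-validation
#' repeated 5 times (25 training/validation runs), with folds stratified on
#' the triage label.
#'
#' @param n_folds number of folds (>= 2).
#' @param n_repeats number of repeats (>= 1).
#' @param seed seed governing fold assignment and the learner RNG.
#' @param params boosted-tree learner parameters.
#' @param nrounds boosting rounds.
#' @param hessian_floor floor for the objective Hessian.
#' @return a `cv_config` list.
#' @export
cv_config <- function(n_folds = 5L, n_repeats = 5L, seed = 1L,
                      params = list(max_depth = 4, eta = 0.1,
                                    subsample = 0.9, colsample_bytree = 0.9),
                      nrounds = 120L, hessian_floor = 1e-6) {
  stopifnot(n_folds >= 2L, n_repeats >= 1L)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), params = params,
                 nrounds = as.integer(nrounds),
                 hessian_floor = hessian_floor),
            class = "cv_config")
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds, so per-fold class counts differ from the cohort
# proportions by at most one patient.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds) {
      stop("stratification error: class ", cl, " has fewer than ",
           n_folds, " members")
    }
    fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Fit one cost-sensitive boosted-tree model
#'
#' Wraps the tree learner with the custom expected-cost softmax objective
#' ([batch_cost_derivatives()]). The base margin is 0 for every class
#' (`base_score = 0`) and a single learner thread is used so results are
#' reproducible.
#'
#' @param X numeric feature matrix.
#' @param y integer triage labels.
#' @param C combined `cost_matrix` used by the objective.
#' @param config a [cv_config()] (learner parameters and Hessian floor).
#' @param seed learner RNG seed.
#' @return an `xgb.Booster`.
#' @export
fit_cost_model <- function(X, y, C, config = cv_config(), seed = config$seed) {
  params <- c(config$params,
              list(num_class = 3, base_score = 0, nthread = 1,
                   seed = as.integer(seed %% .Machine$integer.max)))
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = config$nrounds,
                     objective = make_cost_objective(C, config$hessian_floor),
                     verbose = 0)
}

#' Class probabilities from a fitted model
#'
#' @param model an `xgb.Booster` from [fit_cost_model()].
#' @param X numeric feature matrix.
#' @return n x 3 matrix of softmax probabilities.
#' @export
predict_proba <- function(model, X) {
  softmax_prob(predict(model, X, outputmargin = TRUE))
}

#' Repeated stratified cross-validation with the cost-sensitive learner
#'
#' For each of `n_repeats` repeats the cohort is partitioned into
#' `n_folds` label-stratified folds; a model is trained on each training
#' split and probabilistic predictions recorded on the held-out fold, so
#' every patient is held out exactly once per repeat. Deterministic given
#' the config seed.
#'
#' @param cohort a `triage_cohort` (or list with elements `X`, `y`).
#' @param C combined `cost_matrix` for the training objective.
#' @param config a [cv_config()].
#' @param keep_models keep fitted boosters in the results (needed for
#'   feature-importance extraction; off by default to save memory).
#' @return list of run results, each with `repeat_id`, `fold`, `test_idx`,
#'   `prob` (held-out n_test x 3), `labels`, `runtime` (seconds) and
#'   optionally `model`.
#' @export
run_cv <- function(cohort, C, config = cv_config(), keep_models = FALSE) {
  if (is.data.frame(cohort)) {
    X <- cohort_feature_matrix(cohort)
    y <- derive_labels(cohort)
  } else {
    X <- cohort$X
    y <- cohort$y
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  runs <- list()
  for (r in seq_len(config$n_repeats)) {
    fold <- stratified_folds(y, config$n_folds)
    for (f in seq_len(config$n_folds)) {
      test_idx <- which(fold == f)
      t0 <- proc.time()[["elapsed"]]
      model <- fit_cost_model(X[-test_idx, , drop = FALSE], y[-test_idx], C,
                              config,
                              seed = config$seed + 1000L * r + f)
      prob <- predict_proba(model, X[test_idx, , drop = FALSE])
      run <- list(repeat_id = r, fold = f, test_idx = test_idx,
                  prob = prob, labels = y[test_idx],
                  runtime = proc.time()[["elapsed"]] - t0)
      if (keep_models) run$model <- model
      runs[[length(runs) + 1L]] <- run
    }
  }
  runs
}

# Pool held-out predictions across all runs (each patient appears once per
# repeat).
pool_runs <- function(runs) {
  list(prob = do.call(rbind, lapply(runs, `[[`, "prob")),
       labels = unlist(lapply(runs, `[[`, "labels")),
       run_id = rep(seq_along(runs), vapply(runs, function(r) length(r$labels),
                                            integer(1))))
}

#' Evaluate cross-validation models on an external cohort
#'
#' Applies every fitted model to an independent cohort (the study's
#' external-evaluation design: all 25 CV models scored on the held-out
#' cohort) and summarizes each metric as mean, SD and a 95% t-interval for
#' the mean across models.
#'
#' @param runs result of [run_cv()] with `keep_models = TRUE`.
#' @param external a schema-compatible `triage_cohort`.
#' @param C optional `cost_matrix` for a cost-weighted AUCmu.
#' @param rule decision rule for the hard assignments.
#' @return list with `per_model` (data.frame of metrics per model) and
#'   `summary` (mean/sd/ci_lower/ci_upper per metric).
#' @export
evaluate_external <- function(runs, external, C = NULL, rule = "argmax") {
  if (!all(vapply(runs, function(r) !is.null(r$model), logical(1)))) {
    stop("runs carry no fitted models; rerun run_cv(keep_models = TRUE)")
  }
  X <- cohort_feature_matrix(external)
  y <- derive_labels(external)
  per <- do.call(rbind, lapply(seq_along(runs), function(i) {
    prob <- predict_proba(runs[[i]]$model, X)
    pred <- decide(prob, rule = rule, C = C)
    f1 <- f1_scores(y, pred)
    data.frame(model = i,
               auc_mu = auc_mu(prob, y),
               f1_weighted = f1$f1_weighted,
               f1_ward = f1$f1_per_class[[1]],
               f1_imc = f1$f1_per_class[[2]],
               f1_icu = f1$f1_per_class[[3]])
  }))
  metrics <- setdiff(names(per), "model")
  summ <- do.call(rbind, lapply(metrics, function(m) {
    v <- per[[m]]
    se <- stats::sd(v) / sqrt(length(v))
    half <- if (se > 0) stats::qt(0.975, length(v) - 1L) * se else 0
    data.frame(metric = m, mean = mean(v), sd = stats::sd(v),
               ci_lower = mean(v) - half, ci_upper = mean(v) + half)
  }))
  list(per_model = per, summary = summ)
}

#' Reduced random-search hyperparameter tuning
#'
#' Samples `budget` candidate parameter sets and scores each by the mean
#' held-out expected cost under inner stratified cross-validation, keeping
#' the best. A desk-scale stand-in for large sequential searches: seeded,
#' and the best-so-far score is nonincreasing in the budget for a shared
#' seed stream prefix.
#'
#' @param cohort a `triage_cohort`.
#' @param C combined `cost_matrix`.
#' @param budget number of candidates (>= 1; `0` returns the defaults with
#'   a warning).
#' @param inner_folds folds of the inner CV.
#' @param seed RNG seed.
#' @param nrounds_range integer range boosting rounds are drawn from.
#' @return list with `params`, `nrounds`, `score` and the search `trace`.
#' @export
tune_hyperparameters <- function(cohort, C, budget = 25L, inner_folds = 3L,
                                 seed = 1L, nrounds_range = c(40L, 160L)) {
  default <- cv_config(seed = seed)
  if (budget < 1L) {
    warning("budget 0: returning default learner parameters")
    return(list(params = default$params, nrounds = default$nrounds,
                score = NA_real_, trace = NULL))
  }
  X <- cohort_feature_matrix(cohort)
  y <- derive_labels(cohort)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best <- NULL
  trace <- data.frame(trial = seq_len(budget), score = NA_real_)
  for (t in seq_len(budget)) {
    cand <- list(max_depth = sample(2:6, 1L),
                 eta = exp(stats::runif(1L, log(0.03), log(0.3))),
                 subsample = stats::runif(1L, 0.6, 1),
                 colsample_bytree = stats::runif(1L, 0.6, 1),
                 min_child_weight = sample(1:5, 1L))
    nrounds <- sample(seq(nrounds_range[1], nrounds_range[2]), 1L)
    fold <- stratified_folds(y, inner_folds)
    cfg <- cv_config(seed = seed + t, params = cand, nrounds = nrounds)
    score <- mean(vapply(seq_len(inner_folds), function(f) {
      te <- which(fold == f)
      m <- fit_cost_model(X[-te, , drop = FALSE], y[-te], C, cfg,
                          seed = seed + t)
      P <- predict_proba(m, X[te, , drop = FALSE])
      mean(rowSums(P * unclass(C)[y[te] + 1L, , drop = FALSE]))
    }, numeric(1)))
    trace$score[t] <- score
    if (is.null(best) || score < best$score) {
      best <- list(params = cand, nrounds = nrounds, score = score)
    }
  }
  c(best, list(trace = trace))
}
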
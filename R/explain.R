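#' Gain-based global feature importance
#'
#' Total objective-function gain contributed by splits on each feature
#' across all trees of a fitted booster, read from the tree dump. Features
#' the model never split on are reported as 0.
#'
#' @param model a fitted `xgb.Booster`.
#' @param features optional character vector fixing the output order;
#'   defaults to the model's feature names.
#' @return named numeric vector of total gains, >= 0.
#' @export
gain_importance <- function(model, features = NULL) {
  if (!inherits(model, "xgb.Booster")) stop("model must be a fitted booster")
  if (is.null(features)) features <- xgboost::getinfo(model, "feature_name")
  dump <- xgboost::xgb.model.dt.tree(model = model)
  splits <- dump[dump$Feature != "Leaf", c("Feature", "Gain")]
  out <- stats::setNames(numeric(length(features)), features)
  if (nrow(splits) > 0L) {
    agg <- tapply(splits$Gain, splits$Feature, sum)
    out[names(agg)] <- agg
  }
  out
}

#' Mean-absolute-SHAP feature importance
#'
#' Per-sample, per-class SHAP attributions from the exact tree-path
#' attribution backend, aggregated to one score per feature by averaging
#' absolute values over samples and over the three classes (the two means
#' commute, so the aggregation order is immaterial).
#'
#' @param model a fitted `xgb.Booster`.
#' @param X numeric feature matrix (or a `triage_cohort`).
#' @return named numeric vector of mean |SHAP| per feature.
#' @export
shap_importance <- function(model, X) {
  if (!inherits(model, "xgb.Booster")) stop("model must be a fitted booster")
  if (is.data.frame(X)) X <- cohort_feature_matrix(X)
  contrib <- predict(model, X, predcontrib = TRUE)  # n x class x (p + bias)
  p <- dim(contrib)[3] - 1L
  vals <- contrib[, , seq_len(p), drop = FALSE]
  out <- apply(abs(vals), 3L, mean)
  names(out) <- dimnames(contrib)[[3]][seq_len(p)]
  if (is.null(names(out))) names(out) <- colnames(X)
  out
}

#' SHAP additivity reconstruction error
#'
#' The tree-path attributions plus the base value must reconstruct the raw
#' margin for every sample and class; returns the largest absolute
#' deviation over the supplied samples.
#'
#' @inheritParams shap_importance
#' @return scalar maximum absolute reconstruction error.
#' @export
shap_additivity_error <- function(model, X) {
  if (is.data.frame(X)) X <- cohort_feature_matrix(X)
  contrib <- predict(model, X, predcontrib = TRUE)
  margins <- predict(model, X, outputmargin = TRUE)
  max(abs(apply(contrib, c(1L, 2L), sum) - margins))
}

#' Feature-importance curves across the zeta grid
#'
#' For each zeta of a retrain-mode sweep (run with `keep_models = TRUE`),
#' extracts gain and mean-|SHAP| importance from every cross-validation
#' model and reports the across-run mean and SD for the requested features.
#'
#' @param sweep a `zeta_sweep` produced in retrain mode with kept models.
#' @param cohort the cohort SHAP values are computed on.
#' @param features character vector of feature names (e.g. the top of
#'   [planted_truth()]); defaults to all features.
#' @return data.frame with columns `zeta`, `feature`, `gain_mean`,
#'   `gain_sd`, `shap_mean`, `shap_sd`.
#' @export
importance_vs_zeta <- function(sweep, cohort, features = NULL) {
  stopifnot(inherits(sweep, "zeta_sweep"))
  if (sweep$mode != "retrain" || is.null(sweep$models)) {
    stop("importance curves need per-zeta models: run zeta_sweep(mode = ",
         "\"retrain\", keep_models = TRUE)")
  }
  X <- cohort_feature_matrix(cohort)
  if (is.null(features)) features <- colnames(X)
  rows <- list()
  for (k in seq_along(sweep$models)) {
    gains <- vapply(sweep$models[[k]],
                    function(m) gain_importance(m, colnames(X))[features],
                    numeric(length(features)))
    shaps <- vapply(sweep$models[[k]],
                    function(m) shap_importance(m, X)[features],
                    numeric(length(features)))
    gains <- matrix(gains, nrow = length(features))
    shaps <- matrix(shaps, nrow = length(features))
    for (i in seq_along(features)) {
      rows[[length(rows) + 1L]] <- data.frame(
        zeta = sweep$table$zeta[k], feature = features[i],
        gain_mean = mean(gains[i, ]), gain_sd = stats::sd(gains[i, ]),
        shap_mean = mean(shaps[i, ]), shap_sd = stats::sd(shaps[i, ]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
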
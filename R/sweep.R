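#' Under-, correct- and over-triage rates
#'
#' Ordinal comparison of assigned vs required level: under-triage is the
#' fraction assigned below their true level (the harm-side error),
#' over-triage the fraction above (the resource-side error). The three
#' rates always sum to 1.
#'
#' @param true,predicted integer triage codes of equal, nonzero length.
#' @return named numeric vector `(under, correct, over)`.
#' @export
triage_rates <- function(true, predicted) {
  if (length(true) != length(predicted)) stop("length mismatch")
  if (length(true) == 0L) stop("empty input")
  c(under = mean(predicted < true),
    correct = mean(predicted == true),
    over = mean(predicted > true))
}

#' Sweep the cost weight zeta and record allocation behaviour
#'
#' For every zeta on the grid the combined cost matrix `C(zeta)` is built
#' and cross-validated held-out assignments are scored: allocation
#' fractions over ward/IMC/ICU, under/correct/over-triage rates, the pooled
#' confusion matrix, and the across-run SD of each rate.
#'
#' Two modes: the default `"decision"` mode trains the cross-validation
#' models once, with the objective at `ref_zeta`, and re-decides the pooled
#' held-out probabilities for each grid zeta with the minimum-expected-cost
#' rule under `C(zeta)` — an approximation that keeps dense grids cheap.
#' `"retrain"` mode retrains the full CV at every zeta (training-time cost
#' sensitivity, assignments by argmax) and optionally keeps the per-zeta
#' models for feature-importance curves. The mode is recorded in the
#' result.
#'
#' @param cohort a `triage_cohort`.
#' @param rc,hc resource and harm `cost_matrix` objects.
#' @param zeta_grid sorted numeric grid, typically within `[-5, 5]`.
#' @param config a [cv_config()].
#' @param mode `"decision"` (fast, default) or `"retrain"`.
#' @param ref_zeta training zeta for decision mode.
#' @param keep_models retain fitted models per zeta (retrain mode only).
#' @return a `zeta_sweep` list: `table` (one row per zeta), `confusions`
#'   (list of 3x3 matrices), `mode`, and in decision mode `pooled`
#'   (held-out probabilities and labels), in retrain mode optionally
#'   `models`.
#' @export
zeta_sweep <- function(cohort, rc, hc, zeta_grid, config = cv_config(),
                       mode = c("decision", "retrain"), ref_zeta = 0.975,
                       keep_models = FALSE) {
  mode <- match.arg(mode)
  if (is.unsorted(zeta_grid)) stop("zeta_grid must be sorted ascending")
  if (mode == "decision") {
    runs <- run_cv(cohort, combine_cost(rc, hc, ref_zeta), config)
    pooled <- pool_runs(runs)
    rows <- vector("list", length(zeta_grid))
    confs <- vector("list", length(zeta_grid))
    for (k in seq_along(zeta_grid)) {
      Ck <- combine_cost(rc, hc, zeta_grid[k])
      pred <- decide(pooled$prob, "min_expected_cost", Ck)
      rows[[k]] <- sweep_row(zeta_grid[k], pooled$labels, pred, pooled$run_id)
      confs[[k]] <- confusion_counts(pooled$labels, pred)
    }
    out <- list(table = do.call(rbind, rows), confusions = confs,
                mode = mode, ref_zeta = ref_zeta, pooled = pooled)
  } else {
    rows <- vector("list", length(zeta_grid))
    confs <- vector("list", length(zeta_grid))
    models <- if (keep_models) vector("list", length(zeta_grid)) else NULL
    for (k in seq_along(zeta_grid)) {
      Ck <- combine_cost(rc, hc, zeta_grid[k])
      runs <- run_cv(cohort, Ck, config, keep_models = keep_models)
      pooled <- pool_runs(runs)
      pred <- decide(pooled$prob, "argmax")
      rows[[k]] <- sweep_row(zeta_grid[k], pooled$labels, pred, pooled$run_id)
      confs[[k]] <- confusion_counts(pooled$labels, pred)
      if (keep_models) models[[k]] <- lapply(runs, `[[`, "model")
    }
    out <- list(table = do.call(rbind, rows), confusions = confs,
                mode = mode, models = models)
  }
  class(out) <- "zeta_sweep"
  out
}

sweep_row <- function(zeta, labels, pred, run_id) {
  rates <- triage_rates(labels, pred)
  frac <- as.vector(tabulate(pred + 1L, nbins = 3L)) / length(pred)
  per_run <- vapply(split(seq_along(labels), run_id), function(idx) {
    triage_rates(labels[idx], pred[idx])
  }, numeric(3))
  data.frame(zeta = zeta,
             frac_ward = frac[1], frac_imc = frac[2], frac_icu = frac[3],
             under = rates[["under"]], correct = rates[["correct"]],
             over = rates[["over"]],
             sd_under = stats::sd(per_run["under", ]),
             sd_correct = stats::sd(per_run["correct", ]),
             sd_over = stats::sd(per_run["over", ]))
}

#' Inflection point of the over-triage curve
#'
#' The operating-point heuristic: the grid zeta at which the numerical
#' derivative of the total over-triage rate is maximal — the point past
#' which further increases in zeta buy diminishing under-triage reductions
#' at disproportionate over-triage cost. Derivatives are central
#' differences at interior points and one-sided at the ends; ties resolve
#' to the smallest zeta. An optional odd-width moving-average window
#' smooths the curve first.
#'
#' @param x a `zeta_sweep`, or a numeric grid when `over` is supplied.
#' @param over over-triage rates matching the grid (when `x` is numeric).
#' @param smooth_window odd window width for moving-average smoothing
#'   (1 = none).
#' @return the grid zeta of maximal derivative.
#' @export
inflection_point <- function(x, over = NULL, smooth_window = 1L) {
  if (inherits(x, "zeta_sweep")) {
    zeta <- x$table$zeta
    over <- x$table$over
  } else {
    zeta <- x
  }
  n <- length(zeta)
  if (n < 3L) stop("inflection needs at least 3 grid points")
  if (length(over) != n) stop("grid/curve length mismatch")
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L) stop("smooth_window must be odd")
    half <- (smooth_window - 1L) %/% 2L
    over <- vapply(seq_len(n), function(i) {
      mean(over[max(1L, i - half):min(n, i + half)])
    }, numeric(1))
  }
  d <- numeric(n)
  d[1] <- (over[2] - over[1]) / (zeta[2] - zeta[1])
  d[n] <- (over[n] - over[n - 1]) / (zeta[n] - zeta[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    d[i] <- (over[i + 1] - over[i - 1]) / (zeta[i + 1] - zeta[i - 1])
  }
  # ties (within fp noise of the maximum) resolve to the smallest zeta
  d_max <- max(d)
  zeta[which(d >= d_max - 1e-9 * max(1, abs(d_max)))[1]]
}

#' Bootstrap distribution of the inflection point
#'
#' Runs the cross-validation once, then resamples the pooled held-out
#' (label, probability) pairs with replacement `n_boot` times; each
#' resample's assignments are re-decided across the zeta grid, its
#' over-triage curve rebuilt and its inflection located. Resampling
#' prediction pairs rather than retraining keeps dense grids tractable;
#' pass `retrain = TRUE` for the expensive interpretation in which every
#' bootstrap replicate re-runs the cross-validation on a resampled cohort.
#'
#' @param cohort a `triage_cohort`.
#' @param rc,hc resource and harm cost matrices.
#' @param zeta_grid sorted numeric grid.
#' @param config a [cv_config()].
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param seed resampling seed.
#' @param ref_zeta training zeta for the underlying models.
#' @param retrain re-run the cross-validation per replicate.
#' @return list with `values` (per-replicate inflections), `median`,
#'   `mean`, and `zeta_star` (the median, the operating point).
#' @export
bootstrap_inflection <- function(cohort, rc, hc, zeta_grid,
                                 config = cv_config(), n_boot = 50L,
                                 seed = 1L, ref_zeta = 0.975,
                                 retrain = FALSE) {
  stopifnot(n_boot >= 1L)
  Cs <- lapply(zeta_grid, function(z) unclass(combine_cost(rc, hc, z)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  values <- numeric(n_boot)
  if (retrain) {
    for (b in seq_len(n_boot)) {
      set.seed(seed + b)
      idx <- sample(nrow(cohort), replace = TRUE)
      boot <- cohort[idx, , drop = FALSE]
      boot$patient_id <- sprintf("B%06d", seq_along(idx))
      boot <- as_cohort(as.data.frame(boot))
      sw <- zeta_sweep(boot, rc, hc, zeta_grid,
                       cv_config(n_folds = config$n_folds,
                                 n_repeats = config$n_repeats,
                                 seed = seed + b, params = config$params,
                                 nrounds = config$nrounds,
                                 hessian_floor = config$hessian_floor),
                       mode = "decision", ref_zeta = ref_zeta)
      values[b] <- inflection_point(sw)
    }
  } else {
    runs <- run_cv(cohort, combine_cost(rc, hc, ref_zeta), config)
    pooled <- pool_runs(runs)
    set.seed(seed)
    for (b in seq_len(n_boot)) {
      idx <- sample(length(pooled$labels), replace = TRUE)
      P <- pooled$prob[idx, , drop = FALSE]
      lab <- pooled$labels[idx]
      over <- vapply(Cs, function(Ck) {
        pred <- max.col(-(P %*% Ck), ties.method = "first") - 1L
        mean(pred > lab)
      }, numeric(1))
      values[b] <- inflection_point(zeta_grid, over)
    }
  }
  list(values = values, median = stats::median(values), mean = mean(values),
       zeta_star = stats::median(values))
}
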
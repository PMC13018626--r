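#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability rule (the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose point probability does not exceed the observed table's), the
#' convention of mainstream statistical software.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(133, 939, 6, 75), 2, byrow = TRUE))
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  min(stats::fisher.test(table)$p.value, 1)  # guard fp overshoot past 1
}

#' Summary statistics of one group
#'
#' @param n group size (>= 2).
#' @param mean group mean.
#' @param sd group standard deviation (finite, >= 0).
#' @return a `summary_stat` list.
#' @export
summary_stat <- function(n, mean, sd) {
  stopifnot(n >= 2, is.finite(mean), is.finite(sd), sd >= 0)
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "summary_stat")
}

#' Welch's t-test from printed summary statistics
#'
#' Unequal-variance two-sample t-test computed directly from (n, mean, SD)
#' triples — the form needed when only published summaries are available.
#' `t = (mean_a - mean_b) / sqrt(sd_a^2/n_a + sd_b^2/n_b)` with
#' Welch–Satterthwaite degrees of freedom. Because published summaries are
#' rounded, p-values reproduce source values only to about the second or
#' third decimal.
#'
#' @param a,b `summary_stat` objects (or lists with n/mean/sd).
#' @return list with `t`, `df` and two-sided `p`.
#' @export
#' @examples
#' welch_t_from_summary(summary_stat(1072, 56.85, 14.71),
#'                      summary_stat(81, 56.68, 15.72))
welch_t_from_summary <- function(a, b) {
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  se2 <- va + vb
  if (se2 == 0) {
    if (a$mean == b$mean) stop("zero variance in both groups: t undefined")
    stop("zero standard error with unequal means: t infinite")
  }
  t <- (a$mean - b$mean) / sqrt(se2)
  df <- se2^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test for an r x 2 table
#'
#' For categorical variables with three or more levels (binary variables
#' route to Fisher's exact test instead). No continuity correction;
#' `df = r - 1`. Errors when an expected count is zero — pool sparse
#' categories first.
#'
#' @param table r x 2 matrix of nonnegative counts, r >= 3.
#' @return list with `statistic`, `df` and `p`.
#' @export
chi_square_rx2 <- function(table) {
  table <- as.matrix(table)
  if (ncol(table) != 2L || nrow(table) < 3L) {
    stop("table must be r x 2 with r >= 3 (use fisher_exact_2x2 for 2x2)")
  }
  if (any(table < 0)) stop("counts must be nonnegative")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    stop("expected count of zero: pool empty categories before testing")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

# variables of the comparison battery, with their test routes
battery_spec <- function() {
  list(continuous = c("age", "bmi", "weight", "tumor_volume",
                      "surgery_duration"),
       multicat = c("asa", "gcs", "suspected_diagnosis", "surgical_position"),
       binary_cat = c("sex", "tumor_location"),
       binary = c("preop_deficit", "seizure_history", "hypertension",
                  "coagulation_disorder", "diabetes", "cardiovascular_disease",
                  "pulmonary_disease", "other_disease", "hydrocephalus",
                  "midline_shift", icu_event_columns(), imc_event_columns()))
}

#' Compare two cohorts variable-by-variable
#'
#' The cohort-comparison battery: binary variables (including the 14 event
#' flags and two-level categoricals) go to Fisher's exact test on the 2x2
#' count table; categoricals with more than two levels to the chi-square
#' test (levels absent from both cohorts are dropped first); continuous
#' variables to Welch's t-test on their summary statistics. Three derived
#' composition rows compare the label mix (at least one ICU event; at least
#' one IMC event without ICU; neither). Per-variable failures are reported
#' in the `note` column without aborting the batch.
#'
#' @param a,b schema-compatible `triage_cohort` data.frames.
#' @return data.frame with columns `variable`, `test`, `statistic`, `p`,
#'   `note`.
#' @export
compare_cohorts <- function(a, b) {
  spec <- battery_spec()
  rows <- list()
  add <- function(variable, test, statistic, p, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, test = test, statistic = statistic, p = p,
      note = note, stringsAsFactors = FALSE)
  }
  safely <- function(variable, test, fn) {
    tryCatch(fn(), error = function(e) {
      add(variable, test, NA_real_, NA_real_, note = conditionMessage(e))
    })
  }
  for (v in spec$continuous) {
    safely(v, "welch_t", function() {
      res <- welch_t_from_summary(
        summary_stat(nrow(a), mean(a[[v]]), stats::sd(a[[v]])),
        summary_stat(nrow(b), mean(b[[v]]), stats::sd(b[[v]])))
      add(v, "welch_t", res$t, res$p)
    })
  }
  for (v in c(spec$binary, spec$binary_cat)) {
    safely(v, "fisher_exact", function() {
      xa <- if (v %in% spec$binary_cat) {
        a[[v]] == schema_levels(cohort_schema(), v)[2]
      } else a[[v]] == 1L
      xb <- if (v %in% spec$binary_cat) {
        b[[v]] == schema_levels(cohort_schema(), v)[2]
      } else b[[v]] == 1L
      tab <- rbind(c(sum(xa), sum(!xa)), c(sum(xb), sum(!xb)))
      add(v, "fisher_exact", NA_real_, fisher_exact_2x2(tab))
    })
  }
  for (v in spec$multicat) {
    safely(v, "chi_square", function() {
      lev <- sort(unique(c(a[[v]], b[[v]])))
      tab <- cbind(table(factor(a[[v]], levels = lev)),
                   table(factor(b[[v]], levels = lev)))
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      if (nrow(tab) == 2L) {
        add(v, "fisher_exact", NA_real_, fisher_exact_2x2(t(tab)),
            note = "reduced to 2 levels; routed to Fisher")
      } else {
        res <- chi_square_rx2(tab)
        add(v, "chi_square", res$statistic, res$p)
      }
    })
  }
  la <- derive_labels(a)
  lb <- derive_labels(b)
  comp <- list(icu_any = c(2L), imc_no_icu = c(1L), no_event = c(0L))
  for (nm in names(comp)) {
    safely(nm, "fisher_exact", function() {
      xa <- la %in% comp[[nm]]
      xb <- lb %in% comp[[nm]]
      tab <- rbind(c(sum(xa), sum(!xa)), c(sum(xb), sum(!xb)))
      add(nm, "fisher_exact", NA_real_, fisher_exact_2x2(tab))
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
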
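#' Multiclass AUC (AUCmu) with a partition/cost hook
#'
#' Generalizes the ROC AUC to the three-class problem through pairwise class
#' separability. For each unordered class pair (i, j), every sample is
#' scored by a pairwise decision statistic built from the partition matrix
#' rows `v_i`, `v_j`: samples of class i should score higher than samples
#' of class j, and the pair's separability `A(i, j)` is the rank-sum
#' probability `P(score_i > score_j) + 0.5 P(tie)` over all cross-pairs.
#' AUCmu is the mean of `A(i, j)` over the three pairs. With the default
#' 0/1-misclassification partition the statistic reduces to `p_i - p_j`, so
#' each binary restriction equals the classical rank-sum AUC; passing a
#' combined cost matrix as `partition` gives the cost-weighted variant
#' (scoring-vector substitution).
#'
#' Computed exactly, over all cross-pairs (via midranks), for any n.
#'
#' @param prob n x 3 matrix of class probabilities (rows sum to 1).
#' @param labels integer triage codes of length n; every class must occur.
#' @param partition 3 x 3 partition/cost matrix; defaults to
#'   `1 - diag(3)`.
#' @return scalar in (0, 1).
#' @export
auc_mu <- function(prob, labels, partition = 1 - diag(3)) {
  prob <- as.matrix(prob)
  stopifnot(ncol(prob) == 3L, nrow(prob) == length(labels))
  partition <- unclass(as.matrix(partition))
  present <- sort(unique(labels))
  for (k in 0:2) {
    if (!(k %in% present)) {
      stop("class ", names(triage_levels())[k + 1L],
           " absent from labels; AUCmu pair undefined")
    }
  }
  pairs <- list(c(0L, 1L), c(0L, 2L), c(1L, 2L))
  mean(vapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    pairwise_auc(prob, labels, i, j, partition)
  }, numeric(1)))
}

# Rank-sum A(i, j) for one class pair; class i is oriented to score higher.
pairwise_auc <- function(prob, labels, i, j, partition) {
  keep <- labels %in% c(i, j)
  v <- partition[j + 1L, ] - partition[i + 1L, ]  # i's cheap directions score high
  s <- as.vector(prob[keep, , drop = FALSE] %*% v)
  li <- labels[keep] == i
  n_i <- sum(li); n_j <- sum(!li)
  r <- rank(s)  # midranks handle ties at 1/2
  (sum(r[li]) - n_i * (n_i + 1) / 2) / (n_i * n_j)
}

#' One-vs-rest F1 scores
#'
#' Per-class precision/recall/F1 (F1 = 0 when precision + recall = 0) and
#' the support-weighted mean `sum_k support_k / n * F1_k`.
#'
#' @param true,predicted integer triage codes of equal length.
#' @return list with `f1_weighted` and named `f1_per_class`.
#' @export
f1_scores <- function(true, predicted) {
  if (length(true) != length(predicted)) stop("length mismatch")
  if (length(true) == 0L) stop("empty input")
  f1 <- numeric(3)
  support <- numeric(3)
  for (k in 0:2) {
    tp <- sum(true == k & predicted == k)
    fp <- sum(true != k & predicted == k)
    fn <- sum(true == k & predicted != k)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k + 1L] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    support[k + 1L] <- sum(true == k)
  }
  names(f1) <- names(triage_levels())
  list(f1_weighted = sum(support / length(true) * f1), f1_per_class = f1)
}

#' Confusion matrix of triage assignments
#'
#' Rows index the true acuity class, columns the predicted class.
#'
#' @param true,predicted integer triage codes of equal length.
#' @return 3 x 3 integer matrix of counts.
#' @export
confusion_counts <- function(true, predicted) {
  if (length(true) != length(predicted)) stop("length mismatch")
  if (length(true) == 0L) stop("empty input")
  m <- table(factor(true, levels = 0:2), factor(predicted, levels = 0:2))
  m <- matrix(as.integer(m), 3, 3,
              dimnames = list(true = names(triage_levels()),
                              predicted = names(triage_levels())))
  m
}

#' Full metric report for one prediction set
#'
#' @param prob n x 3 probability matrix.
#' @param labels integer triage codes.
#' @param C optional `cost_matrix`: used for the decision rule (if
#'   `rule = "min_expected_cost"`) and, when `cost_weighted = TRUE`, as the
#'   AUCmu partition.
#' @param rule decision rule passed to [decide()].
#' @param cost_weighted use `C` as the AUCmu partition matrix.
#' @return list with `auc_mu`, `f1_weighted`, `f1_per_class`, `confusion`.
#' @export
metric_report <- function(prob, labels, C = NULL, rule = "argmax",
                          cost_weighted = FALSE) {
  pred <- decide(prob, rule = rule, C = C)
  part <- if (cost_weighted) {
    if (is.null(C)) stop("cost_weighted AUCmu requires a cost matrix")
    C
  } else 1 - diag(3)
  f1 <- f1_scores(labels, pred)
  list(auc_mu = auc_mu(prob, labels, partition = part),
       f1_weighted = f1$f1_weighted,
       f1_per_class = f1$f1_per_class,
       confusion = confusion_counts(labels, pred))
}
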
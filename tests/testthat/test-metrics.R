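# O(n^2) brute-force AUCmu: enumerate all cross-pairs per class pair.
brute_auc_mu <- function(prob, labels, partition = 1 - diag(3)) {
  pair_a <- function(i, j) {
    v <- partition[j + 1, ] - partition[i + 1, ]
    si <- as.vector(prob[labels == i, , drop = FALSE] %*% v)
    sj <- as.vector(prob[labels == j, , drop = FALSE] %*% v)
    tot <- 0
    for (a in si) tot <- tot + sum(a > sj) + 0.5 * sum(a == sj)
    tot / (length(si) * length(sj))
  }
  mean(c(pair_a(0, 1), pair_a(0, 2), pair_a(1, 2)))
}

random_probs <- function(n) {
  p <- matrix(rexp(n * 3), n, 3)
  p / rowSums(p)
}

test_that("AUCmu equals the brute-force pairwise oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 120
    prob <- random_probs(n)
    labels <- sample(0:2, n, TRUE)
    expect_equal(auc_mu(prob, labels), brute_auc_mu(prob, labels),
                 tolerance = 1e-12)
    C <- random_combined_cost()
    expect_equal(auc_mu(prob, labels, partition = unclass(C)),
                 brute_auc_mu(prob, labels, unclass(C)), tolerance = 1e-12)
  }
  # exact agreement at the largest oracle size
  n <- 500
  prob <- random_probs(n)
  labels <- sample(0:2, n, TRUE)
  expect_equal(auc_mu(prob, labels), brute_auc_mu(prob, labels),
               tolerance = 1e-12)
})

test_that("AUCmu is 1 under perfect separation and ~0.5 under permutation", {
  labels <- rep(0:2, each = 20)
  prob <- matrix(0.001, 60, 3)
  prob[cbind(1:60, labels + 1)] <- 0.998
  expect_equal(auc_mu(prob, labels), 1)

  set.seed(22)
  n <- 1e4
  prob <- random_probs(n)
  labels <- sample(0:2, n, TRUE)  # independent of the probabilities
  expect_equal(auc_mu(prob, labels), 0.5, tolerance = 0.02)
})

test_that("binary restriction reduces to the classical rank-sum AUC", {
  set.seed(23)
  n <- 200
  prob <- random_probs(n)
  labels <- sample(0:1, n, TRUE)
  score <- prob[, 1] - prob[, 2]
  r <- rank(score)
  n1 <- sum(labels == 0)
  classical <- (sum(r[labels == 0]) - n1 * (n1 + 1) / 2) /
    (n1 * (n - n1))
  # restrict AUCmu machinery to the (WARD, IMC) pair
  pair <- costtriage:::pairwise_auc(prob, labels, 0L, 1L, 1 - diag(3))
  expect_equal(pair, classical, tolerance = 1e-12)
  # complementing the probabilities (labels fixed) mirrors the AUC
  flipped <- costtriage:::pairwise_auc(1 - prob, labels, 0L, 1L, 1 - diag(3))
  expect_equal(pair + flipped, 1, tolerance = 1e-12)
})

test_that("AUCmu is invariant under monotone transforms of the statistic", {
  set.seed(24)
  n <- 150
  prob <- random_probs(n)
  labels <- sample(0:2, n, TRUE)
  base <- auc_mu(prob, labels)
  # scaling the partition scales every pairwise statistic monotonely
  expect_equal(auc_mu(prob, labels, partition = 7 * (1 - diag(3))), base,
               tolerance = 1e-12)
  expect_error(auc_mu(prob[labels != 2, ], labels[labels != 2]), "ICU")
})

test_that("F1 scores match hand-computed one-vs-rest tables", {
  # truth (W, W, I, U), pred (W, I, I, W): ward has precision = recall = 1/2
  # (one of two predictions and one of two truths correct), IMC precision
  # 1/2 recall 1, ICU all missed — frozen against scikit-learn's f1_score
  truth <- c(0, 0, 1, 2)
  pred <- c(0, 1, 1, 0)
  f1 <- f1_scores(truth, pred)
  expect_equal(unname(f1$f1_per_class), c(1 / 2, 2 / 3, 0))
  expect_equal(f1$f1_weighted, (2 * (1 / 2) + 1 * (2 / 3) + 0) / 4,
               tolerance = 1e-12)

  expect_equal(f1_scores(0:2, 0:2)$f1_weighted, 1)
  expect_equal(unname(f1_scores(0:2, 0:2)$f1_per_class), rep(1, 3))

  # degenerate all-one-class predictor on a balanced set
  truth <- rep(0:2, each = 4)
  pred <- rep(0L, 12)
  f1 <- f1_scores(truth, pred)
  expect_equal(f1$f1_weighted, (1 / 3) * 2 * (1 / 3) / (1 / 3 + 1),
               tolerance = 1e-12)
  expect_error(f1_scores(0:2, 0:1), "length")
  # weighted F1 bounded by the per-class range
  set.seed(25)
  t2 <- sample(0:2, 60, TRUE)
  p2 <- sample(0:2, 60, TRUE)
  f <- f1_scores(t2, p2)
  expect_gte(f$f1_weighted, min(f$f1_per_class))
  expect_lte(f$f1_weighted, max(f$f1_per_class))
})

test_that("confusion matrices count true x predicted and add up", {
  m <- confusion_counts(c(2L), c(0L))
  expect_equal(m["ICU", "WARD"], 1L)
  expect_equal(sum(m), 1L)
  expect_equal(confusion_counts(0:2, 0:2), diag(3),
               ignore_attr = TRUE)
  set.seed(26)
  t1 <- sample(0:2, 30, TRUE); p1 <- sample(0:2, 30, TRUE)
  t2 <- sample(0:2, 40, TRUE); p2 <- sample(0:2, 40, TRUE)
  expect_equal(confusion_counts(c(t1, t2), c(p1, p2)),
               confusion_counts(t1, p1) + confusion_counts(t2, p2))
})
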
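#' Softmax probabilities from raw class scores
#'
#' Numerically stable row-wise softmax.
#'
#' @param z numeric 3-vector of raw scores, or an n x 3 matrix.
#' @return probability vector/matrix of the same shape.
#' @export
softmax_prob <- function(z) {
  if (is.matrix(z)) {
    e <- exp(z - apply(z, 1L, max))
    e / rowSums(e)
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}

cost_row <- function(C, y) unclass(C)[y + 1L, ]

#' Expected misclassification cost of a score vector
#'
#' The training loss of the cost-sensitive objective: with softmax
#' probabilities `p` of the raw scores and true class `y`,
#' `L = sum_k p_k * C[y, k]` — the expected cost of sampling the predicted
#' class from `p`. Minimizing it drives probability mass toward the cheap
#' columns of the true class's cost row, rather than toward the nominal
#' 0/1-error optimum.
#'
#' @param z raw score 3-vector.
#' @param y true class code (0 = WARD, 1 = IMC, 2 = ICU).
#' @param C a `cost_matrix`.
#' @return scalar loss.
#' @export
expected_cost_loss <- function(z, y, C) {
  sum(softmax_prob(z) * cost_row(C, y))
}

#' Analytic gradient and Hessian of the expected-cost loss
#'
#' With `p = softmax(z)`, `c = C[y, ]` and `S = sum_k p_k c_k`:
#' `g_j = p_j (c_j - S)` and, differentiating again along class j,
#' `h_j = p_j (c_j - S)(1 - 2 p_j)` (diagonal approximation). The true
#' second derivative can be negative, which boosted-tree leaf solvers cannot
#' use, so the Hessian is floored at `hessian_floor`. `sum_j g_j = 0`
#' identically (shift invariance of the softmax).
#'
#' @inheritParams expected_cost_loss
#' @param hessian_floor positive lower bound applied to the Hessian.
#' @return list with numeric 3-vectors `gradient` and `hessian`.
#' @export
cost_derivatives <- function(z, y, C, hessian_floor = 1e-6) {
  p <- softmax_prob(z)
  cc <- cost_row(C, y)
  S <- sum(p * cc)
  g <- p * (cc - S)
  h <- pmax(g * (1 - 2 * p), hessian_floor)
  list(gradient = g, hessian = h)
}

#' Row-wise gradient/Hessian for a batch of samples
#'
#' Vectorized form of [cost_derivatives()] matching the layout expected by
#' the boosted-tree library's custom multiclass objective (n x 3 matrices,
#' one column per class).
#'
#' @param Z n x 3 matrix of raw scores.
#' @param y integer vector of n true class codes.
#' @param C a `cost_matrix`.
#' @param hessian_floor positive lower bound applied to the Hessian.
#' @return list of n x 3 matrices `gradient` and `hessian`.
#' @export
batch_cost_derivatives <- function(Z, y, C, hessian_floor = 1e-6) {
  Z <- as.matrix(Z)
  if (nrow(Z) != length(y)) stop("shape mismatch: nrow(Z) != length(y)")
  if (ncol(Z) != 3L) stop("shape mismatch: Z must have 3 columns")
  P <- softmax_prob(Z)
  Cy <- unclass(C)[y + 1L, , drop = FALSE]
  S <- rowSums(P * Cy)
  G <- P * (Cy - S)
  H <- pmax(G * (1 - 2 * P), hessian_floor)
  list(gradient = G, hessian = H)
}

# Objective callback factory for xgboost's custom multiclass API:
# margins in (n x 3), per-sample gradient/hessian matrices out.
make_cost_objective <- function(C, hessian_floor = 1e-6) {
  force(C)
  function(preds, dtrain) {
    y <- xgboost::getinfo(dtrain, "label")
    d <- batch_cost_derivatives(preds, y, C, hessian_floor)
    list(grad = d$gradient, hess = d$hessian)
  }
}

#' Turn class probabilities into a triage assignment
#'
#' Two decision rules: `argmax` picks the most probable class; a
#' `min_expected_cost` picks the column j minimizing
#' `sum_i p_i C[i, j]`, i.e. the cheapest assignment under the cost matrix.
#' Ties resolve to the lowest acuity level in both rules.
#'
#' @param p probability 3-vector or n x 3 matrix.
#' @param rule decision rule.
#' @param C a `cost_matrix`, required for `min_expected_cost`.
#' @return integer triage code(s).
#' @export
#' @examples
#' decide(c(0.2, 0.3, 0.5))                    # ICU
#' decide(c(1, 1, 1) / 3)                      # tie -> WARD
decide <- function(p, rule = c("argmax", "min_expected_cost"), C = NULL) {
  rule <- match.arg(rule)
  P <- if (is.matrix(p)) p else matrix(p, nrow = 1L)
  score <- if (rule == "argmax") {
    P
  } else {
    if (is.null(C)) stop("min_expected_cost requires a cost matrix")
    -(P %*% unclass(C))  # column j of P %*% C is the expected cost of predicting j
  }
  max.col(score, ties.method = "first") - 1L
}
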
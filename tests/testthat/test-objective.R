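test_that("expected-cost loss matches hand-evaluated cases", {
  C <- cost_matrix(rbind(c(0, 1, 1), c(0, 0, 0), c(0, 1, 2)))
  # row of zeros: loss 0 for any score
  expect_equal(expected_cost_loss(c(3, -1, 2), 1L, C), 0)
  # uniform p over row (0, 1, 2): mean of the row
  Cy <- cost_matrix(rbind(c(0, 1, 2), c(0, 0, 0), c(0, 0, 0)))
  expect_equal(expected_cost_loss(c(0, 0, 0), 0L, Cy), 1, tolerance = 1e-12)
  # strongly confident correct prediction on a 0/1 cost row
  p <- softmax_prob(c(10, 0, 0))
  expect_equal(expected_cost_loss(c(10, 0, 0), 0L, C), p[2] + p[3])
  expect_lt(expected_cost_loss(c(10, 0, 0), 0L, C), 1e-4)
})

test_that("analytic gradient and Hessian agree with finite differences", {
  set.seed(101)
  max_g_err <- 0
  max_h_err <- 0
  for (i in 1:200) {
    z <- rnorm(3, sd = 2)
    y <- sample(0:2, 1)
    C <- random_combined_cost()
    d <- cost_derivatives(z, y, C)
    max_g_err <- max(max_g_err, max(abs(d$gradient - fd_gradient(z, y, C))))
    # Hessian: differentiate the analytic gradient component-wise
    eps <- 1e-5
    h_fd <- vapply(1:3, function(j) {
      zp <- z; zm <- z
      zp[j] <- zp[j] + eps
      zm[j] <- zm[j] - eps
      (cost_derivatives(zp, y, C)$gradient[j] -
         cost_derivatives(zm, y, C)$gradient[j]) / (2 * eps)
    }, numeric(1))
    raw_h <- with(list(p = softmax_prob(z)), {
      cc <- unclass(C)[y + 1, ]
      S <- sum(p * cc)
      p * (cc - S) * (1 - 2 * p)
    })
    max_h_err <- max(max_h_err, max(abs(raw_h - h_fd)))
  }
  expect_lt(max_g_err, 1e-6)
  expect_lt(max_h_err, 1e-6)
})

test_that("gradients sum to zero and constant cost rows are flat", {
  set.seed(102)
  for (i in 1:100) {
    z <- rnorm(3, sd = 3)
    y <- sample(0:2, 1)
    C <- random_combined_cost()
    d <- cost_derivatives(z, y, C)
    expect_lt(abs(sum(d$gradient)), 1e-12)
  }
  Cc <- cost_matrix(matrix(0.7, 3, 3))
  d <- cost_derivatives(c(1, -2, 0.5), 2L, Cc)
  expect_equal(unname(d$gradient), rep(0, 3), tolerance = 1e-15)
})

test_that("batch derivatives are a rowwise map with floored Hessians", {
  set.seed(103)
  C <- random_combined_cost()
  Z <- matrix(rnorm(30, sd = 2), 10, 3)
  y <- sample(0:2, 10, TRUE)
  b <- batch_cost_derivatives(Z, y, C)
  one <- cost_derivatives(Z[4, ], y[4], C)
  expect_equal(unname(b$gradient[4, ]), unname(one$gradient), tolerance = 1e-14)
  expect_equal(unname(b$hessian[4, ]), unname(one$hessian), tolerance = 1e-14)
  # permuting rows permutes outputs
  perm <- sample(10)
  bp <- batch_cost_derivatives(Z[perm, ], y[perm], C)
  expect_equal(bp$gradient, b$gradient[perm, ], tolerance = 1e-14)
  # floor holds over many random draws
  Zbig <- matrix(rnorm(3000, sd = 3), 1000, 3)
  ybig <- sample(0:2, 1000, TRUE)
  expect_true(all(batch_cost_derivatives(Zbig, ybig, C)$hessian >= 1e-6))
  expect_error(batch_cost_derivatives(Z, y[1:5], C), "shape")
})

test_that("decision rules break ties toward the lowest acuity", {
  expect_identical(decide(c(0.2, 0.3, 0.5)), 2L)
  expect_identical(decide(c(1, 1, 1) / 3), 0L)
  C <- combine_cost(build_rc(), build_hc(c(0.629, 0.247, 0.124)), 5)
  expect_identical(decide(c(0.6, 0.2, 0.2), "min_expected_cost", C), 2L)
  expect_identical(decide(c(0.6, 0.2, 0.2)), 0L)  # rules diverge at high zeta
  expect_error(decide(c(0.6, 0.2, 0.2), "min_expected_cost"), "cost matrix")
  # uniform cost columns tie -> WARD
  Cu <- cost_matrix(matrix(1, 3, 3))
  expect_identical(decide(c(0.2, 0.5, 0.3), "min_expected_cost", Cu), 0L)
})

test_that("plain 0/1 cost recovers cost-insensitive training on separable data", {
  set.seed(104)
  n <- 300
  y <- sample(0:2, n, TRUE)
  X <- cbind(x1 = y + rnorm(n, sd = 0.05), x2 = rnorm(n))
  C <- cost_matrix(1 - diag(3))
  m <- fit_cost_model(X, y, C, cv_config(nrounds = 60), seed = 1)
  acc <- mean(decide(predict_proba(m, X)) == y)
  expect_gte(acc, 0.99)
  # loss ordering equals (1 - p_y) ordering under 0/1 cost
  z1 <- c(2, 0, 0); z2 <- c(0.5, 0.4, 0)
  expect_identical(
    expected_cost_loss(z1, 0L, C) < expected_cost_loss(z2, 0L, C),
    (1 - softmax_prob(z1)[1]) < (1 - softmax_prob(z2)[1]))
})

test_that("raising the missed-ICU cost never hurts ICU recall", {
  co <- fixture_cohort(600, seed = 9)
  X <- cohort_feature_matrix(co)
  y <- derive_labels(co)
  recalls <- vapply(c(1, 4, 16), function(w) {
    C <- cost_matrix(rbind(c(0, 1, 1), c(1, 0, 1), c(w, w, 0)) / max(w, 1))
    m <- fit_cost_model(X, y, C, cv_config(nrounds = 60), seed = 5)
    pred <- decide(predict_proba(m, X))
    sum(pred == 2 & y == 2) / sum(y == 2)
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
})
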
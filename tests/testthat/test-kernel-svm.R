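test_that("sigma heuristic is the median nearest-negative distance of positives", {
  x <- rbind(c(0, 0), c(4, 0), c(1, 0), c(2, 0), c(9, 0))
  y <- c(1, 1, -1, -1, -1)
  # nearest distances per positive: 1 and 2 -> median 1.5
  expect_equal(sigma_heuristic(x, y), 1.5)
  # single positive: its nearest-negative distance
  expect_equal(sigma_heuristic(x[c(1, 3, 5), ], c(1, -1, -1)), 1)
  # coincident positive/negative triggers the nonzero fallback
  x2 <- rbind(c(0, 0), c(0, 0), c(3, 0))
  expect_equal(sigma_heuristic(x2, c(1, -1, -1)), 3)
  expect_error(sigma_heuristic(rbind(c(0, 0), c(0, 0)), c(1, -1)), "undefined")
  expect_error(sigma_heuristic(x[1:2, ], c(1, 1)), "each class")
})

test_that("sigma heuristic is scale-equivariant and kernel entries scale-invariant", {
  set.seed(21)
  for (i in 1:20) {
    x <- matrix(rnorm(30), 10, 3)
    y <- c(rep(1, 4), rep(-1, 6))
    s <- sigma_heuristic(x, y)
    c_scale <- runif(1, 0.1, 10)
    expect_equal(sigma_heuristic(c_scale * x, y), c_scale * s)
    expect_equal(rbf_kernel(c_scale * x, sigma = c_scale * s),
                 rbf_kernel(x, sigma = s))
  }
})

test_that("RBF kernel has unit diagonal, correct decay, and large-sigma limit", {
  x <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  k <- rbf_kernel(x, sigma = 5)  # ||x1 - x2|| = 5 = sigma
  expect_equal(diag(k), c(1, 1))
  expect_equal(k[1, 2], exp(-1))
  expect_equal(rbf_kernel(x, sigma = 1e8)[1, 2], 1, tolerance = 1e-10)
  expect_error(rbf_kernel(x, sigma = 0), "positive")
  expect_error(rbf_kernel(x, sigma = -1), "positive")
})

test_that("diagonal augmentation follows lambda = m/2 and class-size scaling", {
  set.seed(5)
  x <- matrix(rnorm(100 * 4), 100, 4)
  y <- c(rep(1, 20), rep(-1, 80))
  k <- rbf_kernel(x, sigma = 2)
  ka <- augment_diagonal(k, y)
  expect_equal(ka$m, 1)
  expect_equal(ka$lam, 0.5)
  expect_equal(unname(diag(ka$values)[y == 1]), rep(1.10, 20))
  expect_equal(unname(diag(ka$values)[y == -1]), rep(1.40, 80))
  # off-diagonal untouched
  off <- upper.tri(k)
  expect_identical(ka$values[off], k[off])
  # 1:4 imbalance => negative augmentation exactly 4x the positive one
  expect_equal(unique(ka$aug[y == -1]) / unique(ka$aug[y == 1]), 4)
  # balanced classes: both diagonals 1.25
  yb <- rep(c(1, -1), each = 50)
  expect_equal(unname(unique(diag(augment_diagonal(k, yb)$values))), 1.25)
  expect_error(augment_diagonal(k, y[1:10]), "length")
})

test_that("augmented kernel stays positive semidefinite", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(1, -1)
    ka <- augment_diagonal(rbf_kernel(x, sigma = 1.5), y)
    expect_gte(min(eigen(ka$values, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("two-point problem matches the closed-form dual solution", {
  k_off <- 0.6
  ka <- augment_diagonal(matrix(c(1, k_off, k_off, 1), 2, 2), c(1, -1))
  # both diagonals 1 + 0.5 * 1/2 = 1.25
  expect_equal(unname(diag(ka$values)), c(1.25, 1.25))
  model <- train_svm(ka)
  a_expected <- 1 / (1.25 - k_off)
  expect_equal(model$alpha, rep(a_expected, 2), tolerance = 1e-8)
  expect_equal(model$bias, 0, tolerance = 1e-10)
  # y_i f(x_i) = 1 in the augmented geometry
  f_aug <- drop(ka$values %*% (model$alpha * ka$labels)) + model$bias
  expect_equal(ka$labels * f_aug, c(1, 1), tolerance = 1e-8)
})

test_that("solver satisfies the dual constraints and separates a separable task", {
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c(-1, -1, -1, 1, 1, 1)
  ka <- augment_diagonal(rbf_kernel(x, sigma = 2), y, sigma = 2)
  model <- train_svm(ka)
  expect_true(all(model$alpha >= 0))
  expect_lt(abs(sum(model$alpha * y)), 1e-8)
  f <- discriminants(model, rbf_kernel(x, x, 2))
  expect_equal(sign(f), y)
  # oracle agreement on this task
  ora <- oracle_svm(ka$values, y)
  expect_equal(model$objective, ora$objective, tolerance = 1e-6)
  f_ora <- drop(rbf_kernel(x, x, 2) %*% (ora$alpha * y)) + ora$bias
  expect_equal(f, f_ora, tolerance = 1e-6)
})

test_that("solver matches the exhaustive QP oracle on random small tasks", {
  set.seed(77)
  for (i in 1:40) {
    tk <- random_svm_task(sample(4:10, 1))
    ka <- augment_diagonal(tk$k, tk$y)
    model <- train_svm(ka)
    ora <- oracle_svm(ka$values, tk$y)
    expect_equal(model$objective, ora$objective, tolerance = 1e-6)
    expect_equal(model$alpha, ora$alpha, tolerance = 1e-5)
    f_impl <- discriminants(model, tk$k)
    f_ora <- drop(tk$k %*% (ora$alpha * tk$y)) + ora$bias
    expect_equal(f_impl, f_ora, tolerance = 1e-6)
  }
})

test_that("discriminants validate the cross-kernel orientation and degenerate models", {
  set.seed(8)
  tk <- random_svm_task(8)
  ka <- augment_diagonal(tk$k, tk$y)
  model <- train_svm(ka)
  expect_error(discriminants(model, tk$k[, 1:3]), "match")
  # evaluating training points through the plain kernel is reproducible
  f1 <- discriminants(model, tk$k)
  f2 <- discriminants(model, rbf_kernel(tk$x, tk$x, tk$sigma))
  expect_equal(f1, f2, tolerance = 1e-8)
  # all-zero alpha gives a constant discriminant equal to the bias
  model0 <- model
  model0$alpha <- rep(0, length(model$alpha))
  expect_equal(discriminants(model0, tk$k), rep(model$bias, 8))
})
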
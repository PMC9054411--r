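test_that("kernel evaluations match their closed forms", {
  expect_equal(kernel_eval(c(1, 2), c(3, 4), kernel_spec("linear")), 11)
  expect_equal(kernel_eval(c(1, 0), c(1, 0),
                           kernel_spec("polynomial", degree = 2, coef0 = 1)),
               4)
  expect_equal(kernel_eval(c(1, 2), c(1, 2), kernel_spec("rbf", gamma = 0.5)),
               1)
  u <- c(0, 1); v <- c(1, 0)
  expect_equal(kernel_eval(u, v, kernel_spec("rbf", gamma = 2)), exp(-4))
  expect_error(kernel_eval(1:2, 1:3, kernel_spec("linear")), "dimension")
  expect_error(kernel_spec("rbf", gamma = -1), "gamma")
})

test_that("the symmetric two-point problem is solved analytically", {
  fit <- svm_fit(matrix(c(0, 2), 2, 1), c(-1, 1), kernel = "linear", C = 10)
  expect_equal(fit$N, 1, tolerance = 1e-8)
  expect_equal(fit$a, -1, tolerance = 1e-8)
  expect_equal(fit$beta, c(0.5, 0.5), tolerance = 1e-8)
  expect_setequal(fit$support, c(1, 2))
  # boundary at x = 1; tie resolves to +1
  expect_equal(decision_values(fit, matrix(1)), 0, tolerance = 1e-10)
  expect_equal(predict(fit, matrix(1)), 1)
  expect_equal(decision_values(fit, matrix(2)), 1, tolerance = 1e-8)
})

test_that("an RBF machine separates XOR", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  y <- c(-1, 1, 1, -1)
  fit <- svm_fit(X, y, kernel = kernel_spec("rbf", gamma = 1), C = 10)
  expect_equal(predict(fit, X), y)
})

test_that("SMO matches a dense projected-gradient QP oracle", {
  set.seed(91)
  for (rep in 1:10) {
    X <- matrix(rnorm(20 * 2), 20, 2)
    y <- sign(X[, 1] + 0.5 * rnorm(20)); y[y == 0] <- 1
    if (length(unique(y)) < 2) next
    for (kern in list(kernel_spec("linear"), kernel_spec("rbf", gamma = 0.7))) {
      C <- 1
      fit <- svm_fit(X, y, kernel = kern, C = C, tol = 1e-6)
      K <- deltarad:::kernel_matrix(X, X, kern)
      oracle <- oracle_qp_svm(K, y, C)
      expect_equal(fit$dual_objective, oracle$objective, tolerance = 1e-6)
      # decision signs agree on fresh points
      Xt <- matrix(rnorm(30 * 2), 30, 2)
      f_fit <- decision_values(fit, Xt)
      Kt <- deltarad:::kernel_matrix(Xt, X, kern)
      f_or <- drop(Kt %*% (oracle$alpha * y)) + oracle$bias
      away <- abs(f_or) > 1e-3  # skip points numerically on the boundary
      expect_equal(sign(f_fit[away]), sign(f_or[away]))
    }
  }
})

test_that("KKT conditions and the dual equality hold at convergence", {
  set.seed(92)
  for (rep in 1:5) {
    X <- matrix(rnorm(30 * 3), 30, 3)
    y <- sign(rnorm(30)); y[y == 0] <- 1
    if (length(unique(y)) < 2) next
    C <- 2
    tol <- 1e-4
    fit <- svm_fit(X, y, kernel = kernel_spec("rbf", gamma = 0.5), C = C,
                   tol = tol)
    expect_true(all(fit$beta >= 0 & fit$beta <= C))
    expect_lt(abs(sum(fit$beta * fit$y)), 1e-8)
    f <- decision_values(fit, X)
    yf <- y * f
    ktol <- 10 * tol
    expect_true(all(yf[fit$beta == 0] >= 1 - ktol))
    free <- fit$beta > 0 & fit$beta < C
    expect_true(all(abs(yf[free] - 1) <= ktol))
    expect_true(all(yf[fit$beta == C] <= 1 + ktol))
    # slack consistency with the primal constraints
    expect_true(all(fit$theta >= 0))
    expect_equal(fit$theta, pmax(0, 1 - yf), tolerance = 1e-8)
  }
})

test_that("hinge loss is non-increasing in C; hard-margin limit is attained", {
  set.seed(93)
  X <- matrix(rnorm(40 * 2), 40, 2)
  y <- ifelse(X[, 1] + X[, 2] > 0, 1, -1)
  X <- X + 0.05 * matrix(rnorm(80), 40, 2)  # slight noise, near-separable
  slack <- vapply(c(0.01, 0.1, 1, 10, 100), function(C) {
    sum(svm_fit(X, y, kernel = "linear", C = C, tol = 1e-6)$theta)
  }, numeric(1))
  expect_true(all(diff(slack) <= 1e-6))
  # separable data at large C: SMO reaches the hard-margin QP solution
  Xs <- matrix(c(-2, -1.5, 1.5, 2, 0.3, -0.4, 0.2, -0.1), 4, 2)
  ys <- c(-1, -1, 1, 1)
  fit <- svm_fit(Xs, ys, kernel = "linear", C = 1e4, tol = 1e-8)
  K <- deltarad:::kernel_matrix(Xs, Xs, kernel_spec("linear"))
  oracle <- oracle_qp_svm(K, ys, 1e4)
  expect_equal(fit$dual_objective, oracle$objective, tolerance = 1e-5)
  expect_lt(sum(fit$theta), 1e-6)
})

test_that("linear primal weights reproduce the kernel expansion", {
  set.seed(94)
  X <- matrix(rnorm(25 * 4), 25, 4)
  y <- sign(X %*% c(1, -1, 0.5, 0) + 0.3 * rnorm(25)); y[y == 0] <- 1
  fit <- svm_fit(X, y, kernel = "linear", C = 1, tol = 1e-6)
  expect_equal(fit$N, drop(crossprod(X, fit$beta * fit$y)), tolerance = 1e-12)
  Xt <- matrix(rnorm(10 * 4), 10, 4)
  expect_equal(drop(Xt %*% fit$N) + fit$a, decision_values(fit, Xt),
               tolerance = 1e-10)
})

test_that("sample permutation relabels support indices but nothing else", {
  set.seed(95)
  X <- matrix(rnorm(30 * 2), 30, 2)
  y <- sign(X[, 1] + 0.3 * rnorm(30)); y[y == 0] <- 1
  fit1 <- svm_fit(X, y, kernel = kernel_spec("rbf", gamma = 1), C = 1,
                  tol = 1e-7)
  perm <- sample(30)
  fit2 <- svm_fit(X[perm, ], y[perm], kernel = kernel_spec("rbf", gamma = 1),
                  C = 1, tol = 1e-7)
  expect_equal(fit1$dual_objective, fit2$dual_objective, tolerance = 1e-6)
  Xt <- matrix(rnorm(20 * 2), 20, 2)
  expect_equal(decision_values(fit1, Xt), decision_values(fit2, Xt),
               tolerance = 1e-4)
  expect_setequal(perm[fit2$support], fit1$support)
})

test_that("agreement with an independent SVM library on a separable problem", {
  set.seed(96)
  X <- matrix(rnorm(40 * 2), 40, 2)
  y <- ifelse(X[, 1] - X[, 2] > 0.2, 1, -1)
  fit <- svm_fit(X, y, kernel = kernel_spec("rbf", gamma = 0.5), C = 1,
                 tol = 1e-6)
  ref <- e1071::svm(X, factor(y), kernel = "radial", gamma = 0.5, cost = 1,
                    scale = FALSE)
  Xt <- matrix(rnorm(40 * 2), 40, 2)
  agree <- mean(predict(fit, Xt) == as.numeric(as.character(predict(ref, Xt))))
  expect_gte(agree, 0.95)
})

test_that("training input contracts are enforced", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(svm_fit(X, rep(1, 5)), "single class")
  X2 <- X; X2[1, 1] <- NA
  expect_error(svm_fit(X2, c(1, 1, -1, -1, 1)), "non-finite")
  fit <- svm_fit(X, c(1, 1, -1, -1, 1), kernel = "linear")
  expect_error(decision_values(fit, matrix(1, 1, 3)), "features")
  expect_error(svm_fit(X, c(1, 1, -1, -1, 1), C = 0), "C")
})
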
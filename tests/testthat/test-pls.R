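test_that("a single exact direction is fitted perfectly with one component", {
  X <- matrix(1:4, 4, 1)
  y <- 2 * X[, 1]
  fit <- pls_fit(X, y, ncomp = 1)
  expect_equal(unname(fit$B), 2, tolerance = 1e-12)
  expect_equal(fitted(fit), y, tolerance = 1e-12)
})

test_that("full-rank PLS reproduces ordinary least squares", {
  set.seed(12)
  X <- matrix(rnorm(48), 12, 4)
  y <- drop(X %*% c(1, -2, 0.5, 3)) + rnorm(12)
  fit <- pls_fit(X, y, ncomp = 4)
  ols <- unname(coef(lm(y ~ X))[-1])   # normal-equations oracle
  expect_equal(unname(fit$B), ols, tolerance = 1e-8)
})

test_that("scores are orthogonal and R = W (P'W)^{-1} holds", {
  set.seed(13)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  fit <- pls_fit(X, y, ncomp = 6)
  TtT <- crossprod(fit$T)
  expect_lt(max(abs(TtT - diag(diag(TtT)))), 1e-8 * max(diag(TtT)))
  expect_lt(max(abs(fit$R - fit$W %*% solve(crossprod(fit$P, fit$W)))), 1e-8)
})

test_that("prediction routes X_new B and T_new b agree", {
  set.seed(14)
  X <- matrix(rnorm(150), 15, 10)
  y <- rnorm(15)
  fit <- pls_fit(X, y, ncomp = 5)
  X_new <- matrix(rnorm(50), 5, 10)
  via_B <- predict(fit, X_new)
  T_new <- sweep(X_new, 2, fit$x_center) %*% fit$R
  via_T <- drop(T_new %*% fit$b) + fit$y_center
  expect_lt(max(abs(via_B - via_T)), 1e-10)
  # training rows predict the training fitted values
  expect_equal(predict(fit, X), fitted(fit), tolerance = 1e-12)
  # a row at the training center predicts the training mean
  expect_equal(predict(fit, matrix(fit$x_center, 1)), fit$y_center,
               tolerance = 1e-12)
})

test_that("coefficients are scale equivariant in y and proportional to X'y at a = 1", {
  set.seed(15)
  X <- matrix(rnorm(80), 16, 5)
  y <- rnorm(16)
  f1 <- pls_fit(X, y, ncomp = 3)
  f2 <- pls_fit(X, 5 * y, ncomp = 3)
  expect_equal(5 * f1$B, f2$B, tolerance = 1e-12)
  fa <- pls_fit(X, y, ncomp = 1)
  s <- crossprod(sweep(X, 2, colMeans(X)), y - mean(y))
  cors <- fa$B / drop(s)
  expect_lt(diff(range(cors)), 1e-10 * max(abs(cors)))
})

test_that("deflation shrinks the residual predictor matrix monotonically", {
  set.seed(16)
  X <- matrix(rnorm(120), 12, 10)
  y <- rnorm(12)
  fit <- pls_fit(X, y, ncomp = 5)
  Xc <- sweep(X, 2, fit$x_center)
  norms <- vapply(0:fit$ncomp, function(a) {
    E <- Xc - fit$T[, seq_len(a), drop = FALSE] %*%
      t(fit$P[, seq_len(a), drop = FALSE])
    sum(E^2)
  }, numeric(1))
  expect_true(all(diff(norms) < 1e-10))
})

test_that("duplicating a predictor column leaves the full-rank fit unchanged", {
  # a duplicated column does not enlarge the predictor span, so once the
  # component count reaches the rank the fitted values coincide
  set.seed(17)
  X <- matrix(rnorm(100), 20, 5)
  y <- drop(X %*% rnorm(5)) + rnorm(20)
  f1 <- pls_fit(X, y, ncomp = 5)
  f2 <- pls_fit(cbind(X, X[, 2]), y, ncomp = 5)
  expect_equal(fitted(f2), fitted(f1), tolerance = 1e-8)
})

test_that("extraction stops early on rank-deficient predictors", {
  x1 <- rnorm(10)
  X <- cbind(x1, 2 * x1)
  y <- 3 * x1 + 1
  fit <- pls_fit(X, y, ncomp = 2)
  expect_equal(fit$ncomp, 1L)
  expect_equal(fitted(fit), y, tolerance = 1e-10)
})

test_that("fit and predict validate their inputs", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(pls_fit(X, rnorm(10), ncomp = 3), "min\\(n - 1, p\\)")
  expect_error(pls_fit(X, rep(1, 10), ncomp = 1), "zero variance")
  fit <- pls_fit(X, rnorm(10), 1)
  expect_error(predict(fit, matrix(0, 2, 3)), "columns")
})

test_that("RMSEP selection is deterministic and finds an exact single direction", {
  set.seed(18)
  x1 <- rnorm(50)
  X <- cbind(x1, 2 * x1, -x1)
  y <- 3 * x1 + 1
  s1 <- select_ncomp(X, y, k_folds = 5, ncomp_max = 2, seed = 42)
  s2 <- select_ncomp(X, y, k_folds = 5, ncomp_max = 2, seed = 42)
  expect_identical(s1, s2)
  expect_equal(s1$ncomp, 1L)
  expect_lt(s1$rmsep[1], 1e-10)
})

test_that("RMSEP selection recovers the generative rank of a 3-component signal", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(1000 + s)
    L <- matrix(rnorm(200 * 3), 200, 3)
    X <- L %*% matrix(rnorm(30), 3, 10)      # exactly rank 3
    y <- drop(L %*% c(2, -1, 1)) + rnorm(200, sd = 0.05)
    sel <- select_ncomp(X, y, k_folds = 10, ncomp_max = 6, seed = s)
    hits <- hits + (sel$ncomp == 3L)
  }
  expect_gte(hits / 50, 0.95)
})

test_that("fold construction errors are raised", {
  X <- matrix(rnorm(12), 6, 2)
  expect_error(select_ncomp(X, rnorm(6), k_folds = 1), "at least 2")
  expect_error(select_ncomp(X, rnorm(6), k_folds = 7), "more folds")
})
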
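test_that("a single collinear column is fit perfectly with one component", {
  set.seed(1)
  y <- rnorm(20)
  X <- matrix(y, ncol = 1)
  m <- fit_pls1(X, y, 1)
  expect_lt(max(abs(predict(m, X) - y)), 1e-10)
  expect_equal(fit_metrics(y, predict(m, X))$r2, 1, tolerance = 1e-12)
})

test_that("full-component PLS1 reproduces least-squares predictions", {
  set.seed(2)
  for (i in 1:5) {
    n <- 30; p <- 5
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    m <- fit_pls1(X, y, p)
    # independent closed-form oracle: ordinary least squares with intercept
    ols <- lm.fit(cbind(1, X), y)$fitted.values
    expect_lt(max(abs(predict(m, X) - ols)), 1e-8)
  }
})

test_that("a response orthogonal to X yields the zero-coefficient model", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  z <- rnorm(20)
  Xc <- scale(X, scale = FALSE)
  y <- residuals(lm(z ~ Xc))  # exactly orthogonal to every centered column
  expect_warning(m <- fit_pls1(X, y, 2), "no covariance")
  expect_lt(max(abs(m$coef)), 1e-10)
  expect_lt(max(abs(predict(m, X) - mean(y))), 1e-10)
})

test_that("scores are orthogonal and the factorization matches b", {
  set.seed(4)
  X <- matrix(rnorm(40 * 8), 40, 8)
  y <- X[, 1] - 2 * X[, 5] + rnorm(40, sd = 0.3)
  m <- fit_pls1(X, y, 5)
  G <- crossprod(m$scores)
  nrm <- sqrt(diag(G))
  off <- abs(G) / outer(nrm, nrm)
  expect_lt(max(off[upper.tri(off)]), 1e-8)
  # predictions via b equal predictions via the T, q factorization
  fitted_factorized <- as.numeric(m$scores %*% m$y_loadings) + m$y_mean
  expect_lt(max(abs(fitted_factorized - predict(m, X))), 1e-10)
  # training scores are reproduced by the rotation
  expect_lt(max(abs(pls_scores(m, X) - m$scores)), 1e-8)
})

test_that("an all-zero column changes neither coefficients nor predictions", {
  set.seed(5)
  X <- matrix(rnorm(25 * 4), 25, 4)
  y <- rnorm(25)
  m1 <- fit_pls1(X, y, 3)
  m2 <- fit_pls1(cbind(X, 0), y, 3)
  expect_lt(max(abs(m2$coef[1:4] - m1$coef)), 1e-10)
  expect_lt(abs(m2$coef[5]), 1e-10)
  expect_lt(max(abs(predict(m2, cbind(X, 0)) - predict(m1, X))), 1e-10)
})

test_that("training r2 is non-decreasing in the number of components", {
  set.seed(6)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- rnorm(30)
  m <- fit_pls1(X, y, 8)
  r2 <- vapply(1:8, function(a) {
    fit_metrics(y, predict(m, X, n_lv = a))$r2
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("prediction applies the training centering", {
  set.seed(7)
  X <- matrix(rnorm(45), 15, 3)
  y <- rnorm(15)
  m <- fit_pls1(X, y, 2)
  expect_equal(as.numeric(predict(m, m$x_mean)), m$y_mean)
  expect_error(predict(m, matrix(0, 1, 4)), "columns")
})

test_that("rank deficiency stops early with a recorded component count", {
  set.seed(8)
  base <- matrix(rnorm(30), 15, 2)
  X <- cbind(base, base %*% matrix(c(1, 2, -1, 0.5), 2))  # rank 2
  y <- base %*% c(1, -1) + rnorm(15, sd = 0.01)
  expect_warning(m <- fit_pls1(X, y, 4), "rank exhausted")
  expect_lt(m$n_lv, 4)
  expect_error(fit_pls1(X, rep(1, 15), 2), "zero-variance")
})

test_that("leave-one-out CV matches a hand-rolled loop on a small system", {
  set.seed(9)
  X <- matrix(rnorm(6 * 3), 6, 3)
  y <- rnorm(6)
  cv <- loo_cv(X, y, 2)
  # independent loop over the public fitting API
  manual <- sapply(1:2, function(a) {
    pred <- vapply(1:6, function(i) {
      m <- fit_pls1(X[-i, ], y[-i], a)
      predict(m, X[i, , drop = FALSE])
    }, numeric(1))
    sqrt(mean((y - pred)^2))
  })
  expect_equal(unname(cv$rmsecv_per_lv), manual, tolerance = 1e-10)
})

test_that("CV recovers a noiseless linear signal with one component", {
  set.seed(10)
  # single predictor: the first weight vector is the signal direction
  X <- matrix(rnorm(20), 20, 1)
  cv <- loo_cv(X, 3 * X[, 1], 1)
  expect_lt(cv$rmsecv_per_lv[1], 1e-8)
  expect_equal(cv$chosen_lv, 1)
})

test_that("CV on pure noise chooses few components", {
  set.seed(11)
  chosen <- replicate(20, {
    X <- matrix(rnorm(25 * 10), 25, 10)
    y <- rnorm(25)
    loo_cv(X, y, 8)$chosen_lv
  })
  expect_gte(mean(chosen <= 3), 0.75)
  expect_lte(median(chosen), 2)
})

test_that("max_lv beyond the data budget is clipped with a warning", {
  set.seed(12)
  X <- matrix(rnorm(8 * 5), 8, 5)
  y <- rnorm(8)
  expect_warning(cv <- loo_cv(X, y, 12), "clipped")
  expect_equal(length(cv$rmsecv_per_lv), 5)  # min(n - 2, p) = 5... capped
})

test_that("fit_metrics matches its definition", {
  expect_equal(fit_metrics(c(0, 1), c(0.5, 0.5))$r2, 0)
  expect_equal(fit_metrics(c(0, 1), c(0.5, 0.5))$rmse, 0.5)
  set.seed(13)
  y <- rnorm(50); yh <- rnorm(50)
  m <- fit_metrics(y, yh)
  expect_equal(m$rmse, sqrt(sum((y - yh)^2) / 50), tolerance = 1e-12)
  expect_equal(m$r2, 1 - sum((y - yh)^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
  expect_error(fit_metrics(rep(2, 5), rnorm(5)), "zero-variance")
  expect_error(fit_metrics(1:3, 1:4), "equal length")
})
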
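test_that("single-predictor fits satisfy the soft-threshold solution", {
  x <- matrix(c(1, -1, 1, -1), ncol = 1)
  y <- c(1, 0, 1, 0)                      # x'y(centered) = 2, x'x = 4
  expect_equal(unname(lasso_fit(x, y, 2)$beta), 0.25, tolerance = 1e-10)
  expect_equal(unname(lasso_fit(x, y, 2, standardize = FALSE)$beta), 0.25,
               tolerance = 1e-10)
  expect_equal(lambda_max(x, y), 4)
  expect_equal(unname(lasso_fit(x, y, 4)$beta), 0)
  expect_error(lasso_fit(x, y, -1), "lambda")
})

test_that("full shrinkage at lambda_max, none beyond it, OLS at zero", {
  withr::with_seed(3, {
    X <- matrix(rnorm(200), 40, 5)
    y <- rnorm(40) + X[, 2]
  })
  lm_ <- lambda_max(X, y)
  f <- lasso_fit(X, y, lm_)
  expect_equal(unname(f$beta), rep(0, 5))
  expect_equal(f$intercept, mean(y))
  expect_gt(sum(lasso_fit(X, y, 0.99 * lm_)$beta != 0), 0)
  f0 <- lasso_fit(X, y, 0)
  o <- ols_fit(X, y)
  expect_equal(f0$beta, o$beta, tolerance = 1e-8)
  expect_equal(f0$intercept, o$intercept, tolerance = 1e-8)
  expect_equal(lambda_max(X, y * 0), 0)
})

test_that("ordinary least squares matches the normal equations and flags rank deficiency", {
  withr::with_seed(8, {
    X <- matrix(rnorm(150), 50, 3)
    y <- rnorm(50)
  })
  o <- ols_fit(X, y)
  A <- cbind(1, X)
  cf <- solve(crossprod(A), crossprod(A, y))
  expect_equal(unname(c(o$intercept, o$beta)), as.numeric(cf), tolerance = 1e-10)
  r <- y - A %*% cf
  expect_equal(o$sigma2, sum(r^2) / (50 - 3 - 1), tolerance = 1e-10)

  x1 <- rnorm(20)
  expect_equal(unname(ols_fit(matrix(x1, ncol = 1), 2 * x1 + 1)$beta), 2,
               tolerance = 1e-10)
  xc <- x1 - mean(x1)
  y_orth <- rnorm(20)
  y_orth <- y_orth - mean(y_orth)
  y_orth <- y_orth - xc * sum(xc * y_orth) / sum(xc^2)
  expect_equal(unname(ols_fit(matrix(x1, ncol = 1), y_orth)$beta), 0,
               tolerance = 1e-10)
  expect_error(ols_fit(cbind(x1, x1), rnorm(20)), "rank")
})

test_that("penalty grid is log-spaced, decreasing, anchored at lambda_max", {
  withr::with_seed(5, {
    X <- matrix(rnorm(100), 25, 4)
    y <- rnorm(25)
  })
  g <- lambda_grid(X, y, n_points = 50, ratio = 0.001)
  expect_length(g, 50)
  expect_true(all(diff(g) < 0))
  expect_equal(g[1], lambda_max(X, y))
  expect_equal(g[50], 0.001 * g[1], tolerance = 1e-12)
  expect_equal(diff(log(g)), rep(diff(log(g))[1], 49), tolerance = 1e-10)
  g2 <- lambda_grid(X, y, n_points = 2)
  expect_equal(g2, c(lambda_max(X, y), 0.001 * lambda_max(X, y)))
})

test_that("solver agrees with exhaustive sign-pattern enumeration (p <= 3)", {
  withr::with_seed(17, {
    for (r in 1:25) {
      n <- sample(4:10, 1)
      p <- sample(1:3, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- rnorm(n)
      lam <- runif(1, 0.05, 2 * max(abs(crossprod(X, y))))
      f <- lasso_fit(X, y, lam, standardize = FALSE)
      orac <- enum_lasso(X, y, lam)
      expect_equal(unname(f$beta), unname(orac$b), tolerance = 1e-6,
                   label = paste("instance", r))
    }
  })
})

test_that("solver agrees with glmnet under the 1/(2n) penalty mapping", {
  library(glmnet)
  withr::with_seed(23, {
    for (r in 1:15) {
      n <- sample(20:60, 1)
      p <- sample(2:30, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- rnorm(n) + X[, 1]
      lam <- runif(1, 0.05, 15)
      f <- lasso_fit(X, y, lam, standardize = FALSE)
      g <- glmnet(X, y, lambda = lam / (2 * n), standardize = FALSE,
                  thresh = 1e-14)
      expect_lt(max(abs(f$beta - as.numeric(g$beta))), 2e-6)
      expect_lt(abs(f$intercept - as.numeric(g$a0)), 2e-6)
    }
  })
})

test_that("fitted objective beats reference points and the path is coherent", {
  obj <- function(X, y, f, lam)
    sum((y - f$intercept - X %*% f$beta)^2) + lam * sum(abs(f$beta))
  withr::with_seed(31, {
    X <- matrix(rnorm(30 * 8), 30, 8)
    y <- rnorm(30) + X[, 1] - X[, 3]
  })
  grid <- lambda_grid(X, y, 20, 0.01, standardize = FALSE)
  o <- ols_fit(X, y)
  prev <- NULL
  for (lam in grid) {
    f <- lasso_fit(X, y, lam, standardize = FALSE)
    expect_lte(obj(X, y, f, lam),
               sum((y - mean(y))^2) + 1e-8)                 # zero model
    expect_lte(obj(X, y, f, lam), obj(X, y, o, lam) + 1e-8) # OLS point
    if (!is.null(prev))
      expect_lte(obj(X, y, f, lam), obj(X, y, prev, lam) + 1e-8)
    prev <- f
  }
})
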
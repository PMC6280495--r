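test_that("all censored-data fits collapse to the plain Lasso when nothing is censored", {
  withr::with_seed(12, {
    X <- matrix(rnorm(40 * 6), 40, 6)
    y <- rnorm(40) + 2 * X[, 1]
  })
  ds <- censored_data(y, rep(1, 40), min(y) - 1, X)
  for (lam in c(0.5, 5)) {
    ref <- lasso_fit(X, y, lam)
    g <- gaussian_bj_fit(ds, lam)
    np <- nonpar_bj_fit(ds, lam)
    si <- simple_imputation_fit(ds, lam)
    for (f in list(g, np, si)) {
      expect_lt(max(abs(unname(f$beta) - unname(ref$beta))), 1e-8)
      expect_lt(abs(f$intercept - ref$intercept), 1e-8)
    }
    expect_equal(g$status, "converged")
    expect_equal(g$n_iter, 1L)
    expect_equal(np$status, "converged")
  }
})

test_that("constant substitution halves only censored entries and biases predictions as expected", {
  ds <- make_tobit_ds(60, cens_q = 0.5, seed = 21)
  cens <- ds$delta == 0
  z2 <- ds$z
  z2[cens] <- ds$lod[cens] / 2
  f2 <- simple_imputation_fit(ds, 1, divisor = 2)
  expect_equal(unname(f2$beta), unname(lasso_fit(ds$X, z2, 1)$beta),
               tolerance = 1e-10)
  expect_error(simple_imputation_fit(ds, 1, divisor = 3), "divisor")

  # limit substitution predicts higher on average than half-limit
  # substitution (Monte Carlo over 50%-censored datasets on a positive
  # response scale, where halving the limit lowers the working values)
  diffs <- vapply(1:20, function(r) {
    dsr <- withr::with_seed(1000 + r, {
      x <- rnorm(80)
      yy <- 5 + 2 * x + rnorm(80)
      lodr <- as.numeric(quantile(yy, 0.5))
      censored_data(pmax(yy, lodr), as.numeric(yy > lodr), lodr,
                    matrix(x, ncol = 1, dimnames = list(NULL, "x")))
    })
    p1 <- mean(predict(simple_imputation_fit(dsr, 0.5, 1), dsr$X))
    p2 <- mean(predict(simple_imputation_fit(dsr, 0.5, 2), dsr$X))
    p1 - p2
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("Gaussian BJ imputations stay strictly below the detection limit", {
  ds <- make_tobit_ds(80, cens_q = 0.5, seed = 31)
  f <- gaussian_bj_fit(ds, 0.5)
  cens <- ds$delta == 0
  expect_true(all(f$zstar[cens] < ds$lod[cens]))
  expect_identical(f$zstar[!cens], ds$z[!cens])
  expect_gt(f$sigma2, 0)
  expect_true(f$status %in% c("converged", "oscillated", "max_iter"))
})

test_that("one-step fit equals the first iterate of the full loop bit-for-bit", {
  ds <- make_tobit_ds(60, cens_q = 0.4, seed = 41)
  one <- gaussian_bj_fit(ds, 0.8, one_step = TRUE)
  full1 <- gaussian_bj_fit(ds, 0.8, max_iter = 1)
  expect_identical(one$beta, full1$beta)
  expect_identical(one$sigma2, full1$sigma2)
  expect_identical(one$status, "one_step")
  expect_identical(full1$status, "max_iter")
  expect_identical(one$n_iter, 1L)

  np1 <- nonpar_bj_fit(ds, 0.8, one_step = TRUE)
  npf <- nonpar_bj_fit(ds, 0.8, max_iter = 1)
  expect_identical(np1$beta, npf$beta)
  expect_identical(np1$status, "one_step")
})

test_that("unpenalized Gaussian BJ converges to the Tobit MLE (EM property)", {
  ds <- make_tobit_ds(200, beta = 2, sigma = 1, cens_q = 0.5, seed = 51)
  bj <- gaussian_bj_fit(ds, 0, tol_beta = 1e-7, tol_sigma = 1e-7,
                        tol_impute = 1e-7, max_iter = 2000)
  ml <- tobit_mle(ds)
  expect_equal(unname(bj$beta), unname(ml$beta), tolerance = 1e-3)
  expect_equal(bj$intercept, ml$intercept, tolerance = 1e-3)
  expect_equal(bj$sigma2, ml$sigma2, tolerance = 1e-2)
})

test_that("unpenalized likelihood ascent holds exactly; penalized runs terminate cleanly", {
  ds <- make_tobit_ds(80, cens_q = 0.6, seed = 61)
  # lambda = 0 is exact EM: the observed-data likelihood never worsens
  f0 <- gaussian_bj_fit(ds, 0, max_iter = 300)
  expect_true(all(diff(f0$trace[, "objective"]) <= 1e-8))
  # penalized runs are near-monotone (the penalty weight is not variance
  # rescaled) and always terminate with a declared status
  f <- gaussian_bj_fit(ds, 0.4)
  expect_true(f$status %in% c("converged", "oscillated", "max_iter"))
  obj <- f$trace[, "objective"]
  expect_lt(max(diff(obj)), 1e-3)
  # converging runs are not flagged as oscillating
  f2 <- gaussian_bj_fit(ds, 3)
  if (f2$status == "converged") expect_equal(f2$osc_count, 0L)
  expect_error(gaussian_bj_fit(
    censored_data(c(1, 1, 2), c(0, 0, 1), 1, matrix(1:3, ncol = 1)), 1),
    "uncensored")
})

test_that("non-parametric BJ maps back correctly and bounds imputations by the limit", {
  ds <- make_tobit_ds(80, cens_q = 0.5, seed = 71)
  f <- nonpar_bj_fit(ds, 0.5)
  cens <- ds$delta == 0
  expect_true(all(f$zstar[cens] <= ds$lod[cens] + 1e-10))
  expect_equal(f$zstar[!cens], ds$z[!cens], tolerance = 1e-12)
  expect_equal(f$M, max(ds$z))
  expect_true(f$status %in% c("converged", "oscillated", "max_iter"))
  # slope orientation survives the flip: positive true effect stays positive
  expect_gt(unname(f$beta[1]), 0)
})

test_that("KM residual imputation falls back to the largest mass point beyond the support", {
  curve <- km_fit(c(1, 2, 3), c(1, 1, 1))
  v <- bjlasso:::km_cond_mean_vec(curve, c(0, 2.5, 3, 4))
  expect_equal(v[1], 2)        # all mass above
  expect_equal(v[2], 3)        # only the top jump
  expect_equal(v[3], 3)        # no mass strictly above the top: fallback
  expect_equal(v[4], 4)        # beyond support entirely: the threshold
})
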
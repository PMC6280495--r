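test_that("stratified folds balance censored counts and sizes", {
  delta <- c(rep(0, 4), rep(1, 6))
  f <- stratified_kfold(delta, K = 5, seed = 3)
  sizes <- tabulate(f, 5)
  expect_equal(sizes, rep(2, 5))
  ccounts <- vapply(1:5, function(k) sum(delta[f == k] == 0), numeric(1))
  expect_equal(sort(ccounts), c(0, 1, 1, 1, 1))

  f2 <- stratified_kfold(rep(1, 10), K = 5, seed = 3)
  expect_equal(tabulate(f2, 5), rep(2, 5))

  expect_identical(stratified_kfold(delta, 5, seed = 9),
                   stratified_kfold(delta, 5, seed = 9))
  expect_error(stratified_kfold(delta, 1, 1), "at least 2")
  expect_error(stratified_kfold(delta, 11, 1), "exceeds")
})

test_that("imputation-based squared loss reproduces worked values", {
  # a fit object with prescribed coefficients
  fit <- structure(list(beta = c(x = 1), intercept = 0, sigma2 = 1,
                        lambda = 0, n_iter = 1L, status = "direct"),
                   class = "bj_fit")
  # uncensored fold: plain squared error
  test_ds <- censored_data(c(2, 3), c(1, 1), -10, matrix(c(1, 2), ncol = 1,
                           dimnames = list(NULL, "x")))
  expect_equal(loss_imputed_sq(fit, test_ds, imputer_gaussian()),
               mean(c(2 - 1, 3 - 2)^2))
  expect_equal(loss_imputed_sq(fit, test_ds, imputer_constant(1)),
               mean(c(1, 1)))

  # censored rows whose linear predictor equals the limit contribute the
  # squared half-normal mean under the Gaussian imputer
  test_c <- censored_data(c(1, 1), c(0, 0), 1, matrix(c(1, 1), ncol = 1,
                          dimnames = list(NULL, "x")))
  expect_equal(loss_imputed_sq(fit, test_c, imputer_gaussian()),
               0.7978845608^2, tolerance = 1e-9)

  # a perfect fit on an uncensored fold scores zero
  perf <- structure(list(beta = c(x = 2), intercept = 1, sigma2 = 1,
                         lambda = 0, n_iter = 1L, status = "direct"),
                    class = "bj_fit")
  test_p <- censored_data(c(3, 5), c(1, 1), -10, matrix(c(1, 2), ncol = 1,
                          dimnames = list(NULL, "x")))
  expect_equal(loss_imputed_sq(perf, test_p, imputer_gaussian()), 0)
})

test_that("censoring-aware Gaussian loss matches its closed-form cases", {
  fit <- structure(list(beta = c(x = 0), intercept = 0, sigma2 = 1,
                        lambda = 0, n_iter = 1L, status = "direct"),
                   class = "bj_fit")
  # one uncensored row with residual 1 plus one censored row at mu = lod
  mix <- censored_data(c(1, 0), c(1, 0), c(-10, 0),
                       matrix(c(0, 0), ncol = 1,
                              dimnames = list(NULL, "x")))
  expect_equal(loss_gaussian(fit, mix), 1 + 2 * log(2), tolerance = 1e-12)

  # uncensored fold: identical to the squared loss
  unc <- censored_data(c(0.5, -0.2, 1), c(1, 1, 1), -10,
                       matrix(0, 3, 1, dimnames = list(NULL, "x")))
  expect_equal(loss_gaussian(fit, unc), mean(c(0.5, -0.2, 1)^2))

  # a censored row whose linear predictor sits far below its limit is
  # fully explained and contributes nothing
  deep <- censored_data(c(1, 40), c(1, 0), c(-50, 40),
                        matrix(0, 2, 1, dimnames = list(NULL, "x")))
  expect_equal(loss_gaussian(fit, deep), 1, tolerance = 1e-10)
  expect_gte(loss_gaussian(fit, deep), 0)

  allc <- censored_data(c(0, 0), c(0, 0), 0,
                        matrix(0, 2, 1, dimnames = list(NULL, "x")))
  expect_error(loss_gaussian(fit, allc), "uncensored")
  nofit <- structure(list(beta = c(x = 0), intercept = 0, sigma2 = NULL),
                     class = "bj_fit")
  expect_error(loss_gaussian(nofit, unc), "sigma2")
})

test_that("cross-validation is deterministic, anchored at the null model, and leak-free", {
  ds <- make_tobit_ds(60, cens_q = 0.3, seed = 44)
  cv1 <- cv_select_lambda(ds, "lod", "imputed_sq", K = 5, seed = 7,
                          n_lambda = 30)
  cv2 <- cv_select_lambda(ds, "lod", "imputed_sq", K = 5, seed = 7,
                          n_lambda = 30)
  expect_identical(cv1$cv_mean, cv2$cv_mean)
  expect_identical(cv1$lambda_opt, cv2$lambda_opt)
  expect_equal(cv1$lambdas[which.min(cv1$cv_mean)], cv1$lambda_opt)
  expect_true(all(diff(cv1$lambdas) < 0))

  # at lambda_max every fold fits the intercept-only model
  folds <- cv1$fold_assignment
  null_loss <- vapply(1:5, function(k) {
    learn <- ds$z[folds != k]
    mu <- mean(learn)
    zt <- ds$z[folds == k]
    mean((zt - mu)^2)
  }, numeric(1))
  expect_equal(cv1$cv_mean[1], mean(null_loss), tolerance = 1e-10)

  # canary: the learning fit never sees held-out rows
  k <- 1
  learn_idx <- which(folds != k)
  f_before <- fit_method(bjlasso:::subset_censored(ds, learn_idx),
                         "gaussbj", cv1$lambda_opt)
  ds_pert <- ds
  ds_pert$z[folds == k] <- ds_pert$z[folds == k] + 100
  ds_pert$lod[folds == k] <- ds_pert$lod[folds == k] + 100
  f_after <- fit_method(bjlasso:::subset_censored(ds_pert, learn_idx),
                        "gaussbj", cv1$lambda_opt)
  expect_identical(f_before$beta, f_after$beta)
})

test_that("path fits agree with single fits where trajectories coincide", {
  ds <- make_tobit_ds(50, cens_q = 0.4, seed = 55)
  ctx <- suppressWarnings(bjlasso:::design_context(ds$X, TRUE))
  grid <- lambda_grid(ds$X, ds$z, 10, 0.01)
  # substitution baseline: unique solutions, must match everywhere
  path <- bjlasso:::fit_path(ds, "lod", grid, ctx)
  for (l in c(1, 5, 10)) {
    f <- fit_method(ds, "lod", grid[l])
    expect_equal(path$Beta[, l], unname(f$beta), tolerance = 1e-8)
    expect_equal(path$intercepts[l], f$intercept, tolerance = 1e-8)
  }
  # BJ methods start both trajectories from zero at the top of the path
  pg <- bjlasso:::fit_path(ds, "gaussbj", grid, ctx)
  fg <- gaussian_bj_fit(ds, grid[1])
  expect_equal(pg$Beta[, 1], unname(fg$beta), tolerance = 1e-10)
  expect_equal(pg$sigma2[1], fg$sigma2, tolerance = 1e-10)

  # held-out losses from the path equal the single-fit losses
  test_ds <- make_tobit_ds(30, cens_q = 0.4, seed = 56)
  pl <- bjlasso:::path_losses(pg, ds, test_ds, "gaussbj", "gaussian")
  fit1 <- structure(list(beta = stats::setNames(pg$Beta[, 1], colnames(ds$X)),
                         intercept = pg$intercepts[1],
                         sigma2 = pg$sigma2[1]), class = "bj_fit")
  expect_equal(pl[1], loss_gaussian(fit1, test_ds), tolerance = 1e-10)
  pl2 <- bjlasso:::path_losses(pg, ds, test_ds, "gaussbj", "imputed_sq")
  expect_equal(pl2[1], loss_imputed_sq(fit1, test_ds, imputer_gaussian()),
               tolerance = 1e-10)
})

test_that("Kaplan-Meier held-out imputer conditions on learning residuals", {
  ds <- make_tobit_ds(60, cens_q = 0.4, seed = 66)
  fit <- nonpar_bj_fit(ds, 1)
  test_ds <- make_tobit_ds(25, cens_q = 0.4, seed = 67)
  ytilde <- imputer_km(ds)(test_ds, fit)
  cens <- test_ds$delta == 0
  expect_identical(ytilde[!cens], test_ds$z[!cens])
  expect_true(all(ytilde[cens] <= test_ds$lod[cens] + 1e-10))
  l <- loss_imputed_sq(fit, test_ds, imputer_km(ds))
  expect_true(is.finite(l) && l >= 0)
})
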
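test_that("truncated-normal conditional mean matches quadrature across the tail", {
  expect_equal(gaussian_conditional_mean(0, 1, 0), -0.7978845608, tolerance = 1e-9)
  expect_equal(gaussian_conditional_mean(2, 1, 0), quad_trunc_mean(2, 1, 0),
               tolerance = 1e-3)
  # far-upper-tail truncation leaves the mean untouched
  expect_lt(abs(gaussian_conditional_mean(0, 1, 10)), 1e-20)
  for (a in seq(-8, 8, by = 0.5)) {
    expect_equal(gaussian_conditional_mean(0, 1, a),
                 quad_trunc_mean(0, 1, a), tolerance = 1e-8,
                 label = paste("a =", a))
    expect_equal(gaussian_conditional_mean(1.3, 2.1, 1.3 + 2.1 * a),
                 quad_trunc_mean(1.3, 2.1, 1.3 + 2.1 * a), tolerance = 1e-8)
  }
  # strictly below the truncation point, strictly increasing in mu
  mus <- seq(-3, 3, by = 0.25)
  vals <- gaussian_conditional_mean(mus, 1, 0.5)
  expect_true(all(vals < 0.5))
  expect_true(all(diff(vals) > 0))
  expect_error(gaussian_conditional_mean(0, -1, 0), "sigma")
  expect_error(gaussian_conditional_mean(Inf, 1, 0), "finite")
})

test_that("truncated-normal conditional variance matches quadrature and stays in (0, sigma^2]", {
  expect_equal(gaussian_conditional_var(0, 1, 0), 1 - 2 / pi, tolerance = 1e-7)
  expect_equal(gaussian_conditional_var(0, 2, 0), 4 * (1 - 2 / pi),
               tolerance = 1e-6)
  expect_equal(gaussian_conditional_var(0, 1, 50), 1, tolerance = 1e-10)
  for (a in seq(-8, 8, by = 0.5)) {
    v <- gaussian_conditional_var(0, 1, a)
    expect_equal(v, quad_trunc_var(0, 1, a), tolerance = 1e-8,
                 label = paste("a =", a))
    expect_gt(v, 0)
    expect_lte(v, 1)
  }
})

test_that("product-limit estimator reproduces hand computations with tail correction", {
  cv <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(cv$times, c(1, 3))
  expect_equal(cv$jumps, c(1 / 3, 2 / 3))
  expect_equal(cv$surv, c(2 / 3, 0))

  # all events: empirical distribution
  cv2 <- km_fit(c(4, 1, 3, 2), rep(1, 4))
  expect_equal(cv2$jumps, rep(1 / 4, 4))
  expect_equal(sum(cv2$jumps * cv2$times), mean(1:4))

  # largest observation censored gets the remaining mass
  cv3 <- km_fit(c(1, 2), c(1, 0))
  expect_equal(cv3$jumps, c(0.5, 0.5))
  expect_equal(sum(cv3$jumps), 1)

  expect_error(km_fit(numeric(0), numeric(0)), "empty")
  expect_error(km_fit(c(1, 2), c(0, 1) * 0), "censored")
})

test_that("product-limit jumps agree with survival::survfit on random censored samples", {
  withr::with_seed(7, {
    for (r in 1:25) {
      n <- sample(3:30, 1)
      v <- round(rexp(n), 2)            # rounding forces ties
      e <- rbinom(n, 1, 0.6)
      if (!any(e == 1)) e[1] <- 1
      mine <- km_fit(v, e)
      orac <- survfit_jumps(v, e)
      expect_equal(mine$times, orac$times)
      expect_equal(mine$jumps, orac$jumps, tolerance = 1e-12)
      expect_true(all(diff(mine$surv) <= 1e-12))
      expect_equal(sum(mine$jumps), 1, tolerance = 1e-12)
    }
  })
})

test_that("KM conditional mean equals jump-set enumeration for all small samples", {
  cv <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_conditional_mean(cv, 2), 3)
  cv2 <- km_fit(1:4, rep(1, 4))
  expect_equal(km_conditional_mean(cv2, 0), mean(1:4))
  expect_error(km_conditional_mean(cv2, 5), "support")

  value_sets <- list(c(1, 2), c(1, 1), c(1, 2, 3), c(1, 2, 2),
                     c(1, 2, 3, 4), c(2, 2, 3, 3), c(1, 2, 3, 4, 5),
                     c(1, 1, 2, 3, 3, 4))
  for (v in value_sets) {
    n <- length(v)
    for (mask in seq_len(2^n) - 1) {
      e <- as.numeric(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (!any(e == 1)) next
      curve <- km_fit(v, e)
      for (c0 in c(min(v) - 0.5, v, v + 0.5)) {
        orac <- enum_km_cond_mean(v, e, c0)
        if (is.na(orac)) {
          expect_error(km_conditional_mean(curve, c0), "support")
        } else {
          expect_equal(km_conditional_mean(curve, c0), orac, tolerance = 1e-10)
          expect_gt(km_conditional_mean(curve, c0), c0)
        }
      }
    }
  }
})

test_that("Gaussian response imputation fills censored rows below their limits", {
  ds <- make_tobit_ds(40, cens_q = 0.4, seed = 11)
  beta <- 1.5
  z1 <- impute_responses_gaussian(ds, beta, 0.2, 1)
  unc <- ds$delta == 1
  expect_identical(z1[unc], ds$z[unc])
  expect_true(all(z1 <= ds$z + 1e-12))
  expect_true(all(z1[!unc] < ds$lod[!unc]))

  # linear predictor exactly at the limit: shift by the half-normal mean
  ds2 <- censored_data(c(1, 2, 3), c(0, 1, 1), 1,
                       matrix(c(0, 1, 2), ncol = 1))
  z2 <- impute_responses_gaussian(ds2, 0, 1, 1)
  expect_equal(z2[1], 1 - 0.7978845608, tolerance = 1e-9)

  ds3 <- make_tobit_ds(20, cens_q = 0, seed = 2)
  expect_identical(impute_responses_gaussian(ds3, 1, 0, 1), ds3$z)
})
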
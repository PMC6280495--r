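#' Stratified K-fold assignment preserving the censoring proportion
#'
#' Censored and uncensored indices are shuffled independently (seeded) and
#' dealt round-robin, so every fold carries the same number of censored
#' observations up to one, and fold sizes differ by at most one.
#'
#' @param delta 0/1 censoring indicator vector (1 = uncensored).
#' @param K number of folds, `2 <= K <= n`.
#' @param seed integer seed; the same seed always yields the same assignment.
#' @return integer vector of fold labels in `1:K`.
#' @export
stratified_kfold <- function(delta, K, seed = 1) {
  n <- length(delta)
  K <- as.integer(K)
  if (K < 2) stop("K must be at least 2")
  if (K > n) stop("K exceeds the number of observations")
  cens <- which(delta == 0)
  unc <- which(delta == 1)
  ord <- with_seed(seed, {
    c(cens[sample.int(length(cens))], unc[sample.int(length(unc))])
  })
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(K), n)
  folds
}

#' Imputation-based squared cross-validation loss
#'
#' Mean squared difference on a held-out fold between the linear predictor of
#' the learning-fold fit and working responses in which censored test values
#' are replaced by a conditional expectation estimated from the learning data
#' (the `imputer`). On a fully uncensored fold this is the plain squared
#' error loss.
#'
#' @param fit_learn `bj_fit` estimated on the learning folds.
#' @param test held-out [censored_data()].
#' @param imputer `function(test, fit_learn)` returning the working response
#'   vector; see [imputer_gaussian()], [imputer_km()], [imputer_constant()].
#' @return mean squared loss on the fold.
#' @export
loss_imputed_sq <- function(fit_learn, test, imputer) {
  ytilde <- imputer(test, fit_learn)
  mean((ytilde - predict(fit_learn, test$X))^2)
}

#' @rdname loss_imputed_sq
#' @export
imputer_gaussian <- function() {
  function(test, fit) {
    if (is.null(fit$sigma2)) stop("fit carries no sigma2")
    impute_responses_gaussian(test, fit$beta, fit$intercept, fit$sigma2)
  }
}

#' @rdname loss_imputed_sq
#' @param learn learning-fold [censored_data()] whose residuals build the
#'   Kaplan-Meier curve.
#' @export
imputer_km <- function(learn) {
  function(test, fit) {
    # flipped residuals of the learning data: (M - z) - (M - mu) = mu - z
    curve <- km_fit(predict(fit, learn$X) - learn$z, learn$delta)
    ytilde <- test$z
    cens <- test$delta == 0
    if (any(cens)) {
      mu <- predict(fit, test$X[cens, , drop = FALSE])
      ytilde[cens] <- mu - km_cond_mean_vec(curve, mu - test$lod[cens])
    }
    ytilde
  }
}

#' @rdname loss_imputed_sq
#' @param divisor 1 or 2: impute the detection limit or half of it.
#' @export
imputer_constant <- function(divisor = 1) {
  function(test, fit) {
    ytilde <- test$z
    cens <- test$delta == 0
    ytilde[cens] <- test$lod[cens] / divisor
    ytilde
  }
}

#' Censoring-aware Gaussian cross-validation loss
#'
#' Loss that lets censored and uncensored held-out observations contribute on
#' the likelihood scale:
#' `(1/n_unc) sum_unc (z - mu)^2 + (2 sigma^2 / n_unc) sum_cens -ln Phi((lod - mu)/sigma)`,
#' with `sigma^2` estimated on the learning folds. Proportional and
#' equivalent to the negative Gaussian log-likelihood while remaining
#' comparable to the squared loss; it reduces to the squared error term on a
#' fully uncensored fold.
#'
#' @inheritParams loss_imputed_sq
#' @return the loss value (always `>= 0`).
#' @export
loss_gaussian <- function(fit_learn, test) {
  if (is.null(fit_learn$sigma2)) stop("fit carries no sigma2")
  unc <- test$delta == 1
  n_unc <- sum(unc)
  if (n_unc == 0) stop("no uncensored rows in fold")
  mu <- predict(fit_learn, test$X)
  s2 <- fit_learn$sigma2
  sq <- sum((test$z[unc] - mu[unc])^2) / n_unc
  pen <- if (any(!unc))
    (2 * s2 / n_unc) *
      sum(-stats::pnorm((test$lod[!unc] - mu[!unc]) / sqrt(s2), log.p = TRUE))
  else 0
  sq + pen
}

# Fit one of the candidate methods at a single penalty value. `ctx` and
# `beta_init` (standardized left-scale coefficients) enable warm starts along
# a penalty path. All returned fits carry a sigma2 (uncensored residual
# variance when the method itself does not estimate one) so either CV loss
# can be evaluated.
fit_method <- function(ds, method, lambda, ctx = NULL, beta_init = NULL,
                       bj_opts = list()) {
  if (is.null(ctx)) ctx <- suppressWarnings(design_context(ds$X, TRUE))
  fit <- switch(method,
    lod = ,
    lod2 = {
      z <- ds$z
      cens <- ds$delta == 0
      if (method == "lod2") z[cens] <- ds$lod[cens] / 2
      s <- cd_solve(ctx, z, lambda, beta_init)
      new_bj_fit(s$beta, s$intercept, lambda = lambda, status = "direct",
                 beta_std = s$beta_std, names = colnames(ds$X))
    },
    gaussbj = do.call(gaussian_bj_fit,
      c(list(ds = ds, lambda = lambda, ctx = ctx, beta_init = beta_init),
        bj_opts)),
    gaussbj_1step = do.call(gaussian_bj_fit,
      c(list(ds = ds, lambda = lambda, ctx = ctx, beta_init = beta_init,
             one_step = TRUE), bj_opts)),
    nonparbj = do.call(nonpar_bj_fit,
      c(list(ds = ds, lambda = lambda, ctx = ctx,
             beta_init = if (is.null(beta_init)) NULL else -beta_init),
        bj_opts)),
    stop("unknown method '", method, "'")
  )
  if (is.null(fit$sigma2)) {
    unc <- ds$delta == 1
    r <- ds$z[unc] - predict(fit, ds$X[unc, , drop = FALSE])
    fit$sigma2 <- mean(r^2)
  }
  fit
}

bj_opt_or <- function(bj_opts, name, default) {
  if (is.null(bj_opts[[name]])) default else bj_opts[[name]]
}

# Fit a method along the whole decreasing penalty grid on one learning fold
# (warm starts handled inside the compiled path engines). Returns
# original-scale coefficient matrix (p x L), intercepts, per-lambda sigma2
# (uncensored residual variance when the method does not estimate one) and
# termination statuses.
fit_path <- function(ds, method, grid, ctx, bj_opts = list()) {
  L <- length(grid)
  statuses <- rep("direct", L)
  sigma2s <- NULL
  if (method %in% c("lod", "lod2")) {
    z <- ds$z
    cens <- ds$delta == 0
    if (method == "lod2") z[cens] <- ds$lod[cens] / 2
    my <- mean(z)
    Bw <- lasso_path_engine(ctx$G, crossprod(ctx$Xw, z - my), grid)
    mys <- rep(my, L)
  } else if (method %in% c("gaussbj", "gaussbj_1step")) {
    res <- gauss_bj_path_engine(
      ctx$Xw, ctx$G, ds$z, ds$delta, ds$lod, grid,
      bj_opt_or(bj_opts, "max_iter", 100),
      bj_opt_or(bj_opts, "tol_beta", 1e-4),
      bj_opt_or(bj_opts, "tol_sigma", 1e-4),
      bj_opt_or(bj_opts, "tol_impute", 1e-4),
      bj_opt_or(bj_opts, "osc_limit", 3),
      method == "gaussbj_1step",
      identical(bj_opt_or(bj_opts, "sigma_update", "em"), "em"))
    Bw <- res$beta_std
    mys <- as.numeric(res$my)
    sigma2s <- as.numeric(res$sigma2)
    statuses <- bj_statuses[as.integer(res$status) + 1]
  } else if (method == "nonparbj") {
    fl <- flip_censoring(ds, "auto")
    res <- nonpar_bj_path_engine(
      ctx$Xw, ctx$G, fl$y_flip, ds$delta, grid,
      bj_opt_or(bj_opts, "max_iter", 100),
      bj_opt_or(bj_opts, "tol_beta", 1e-4),
      bj_opt_or(bj_opts, "tol_impute", 1e-4),
      bj_opt_or(bj_opts, "osc_limit", 3), FALSE)
    Bw <- -res$beta_std
    mys <- fl$M - as.numeric(res$my)
    statuses <- bj_statuses[as.integer(res$status) + 1]
  } else stop("unknown method '", method, "'")
  Beta <- matrix(0, length(ctx$keep), L)
  Beta[ctx$keep, ] <- Bw / ctx$scales
  intercepts <- mys - colSums(Bw * (ctx$centers / ctx$scales))
  if (is.null(sigma2s)) {
    unc <- ds$delta == 1
    mu_unc <- sweep(ds$X[unc, , drop = FALSE] %*% Beta, 2, intercepts, "+")
    sigma2s <- colMeans((ds$z[unc] - mu_unc)^2)
  }
  list(Beta = Beta, intercepts = intercepts, sigma2 = sigma2s,
       statuses = statuses)
}

# Held-out losses for every penalty on the grid at once.
path_losses <- function(path, learn, test, method, loss_type) {
  L <- ncol(path$Beta)
  mu_t <- sweep(test$X %*% path$Beta, 2, path$intercepts, "+")
  cens <- test$delta == 0
  unc <- !cens
  if (loss_type == "gaussian") {
    n_unc <- sum(unc)
    if (n_unc == 0) stop("no uncensored rows in fold")
    sq <- colSums((test$z[unc] - mu_t[unc, , drop = FALSE])^2) / n_unc
    if (!any(cens)) return(sq)
    sig_row <- rep(sqrt(path$sigma2), each = sum(cens))
    a <- (test$lod[cens] - mu_t[cens, , drop = FALSE]) / sig_row
    sq + (2 * path$sigma2 / n_unc) *
      colSums(-stats::pnorm(a, log.p = TRUE))
  } else {
    Ytilde <- matrix(test$z, nrow = length(test$z), ncol = L)
    if (any(cens)) {
      if (method %in% c("gaussbj", "gaussbj_1step")) {
        sig_row <- rep(sqrt(path$sigma2), each = sum(cens))
        a <- (test$lod[cens] - mu_t[cens, , drop = FALSE]) / sig_row
        h <- exp(stats::dnorm(a, log = TRUE) -
                   stats::pnorm(a, log.p = TRUE))
        Ytilde[cens, ] <- mu_t[cens, , drop = FALSE] - sig_row * h
      } else if (method == "nonparbj") {
        mu_l <- sweep(learn$X %*% path$Beta, 2, path$intercepts, "+")
        for (l in seq_len(L)) {
          curve <- km_fit(mu_l[, l] - learn$z, learn$delta)
          Ytilde[cens, l] <- mu_t[cens, l] -
            km_cond_mean_vec(curve, mu_t[cens, l] - test$lod[cens])
        }
      } else if (method == "lod2") {
        Ytilde[cens, ] <- test$lod[cens] / 2
      }                                  # lod: z already equals the limit
    }
    colMeans((Ytilde - mu_t)^2)
  }
}

#' Cross-validated penalty selection for censored-outcome Lasso methods
#'
#' Runs stratified K-fold cross-validation over a shared log-spaced penalty
#' grid (built from the full data after detection-limit substitution) and
#' returns the penalty minimizing the mean fold loss. The Buckley-James
#' methods run their full iterative loop on every learning fold at every
#' grid value, warm-started along the path from the largest penalty down.
#' Ties in the minimum are broken toward the larger penalty (the grid is
#' decreasing and the first minimizer is kept).
#'
#' @param ds a [censored_data()] object.
#' @param method one of `"gaussbj"`, `"gaussbj_1step"`, `"nonparbj"`,
#'   `"lod"`, `"lod2"`.
#' @param loss_type `"imputed_sq"` (conditional-mean substituted squared
#'   loss) or `"gaussian"` (censoring-aware likelihood loss). For non-BJ
#'   methods the Gaussian loss uses the uncensored residual variance of the
#'   learning fit (a non-canonical combination, accepted with a message in
#'   the returned object).
#' @param K folds (5 is the simulation default; 20 suits sparse binary
#'   predictors on real data).
#' @param seed integer seed controlling the fold assignment.
#' @param n_lambda,lambda_min_ratio penalty-grid size and span.
#' @param bj_opts list of options passed to the Buckley-James fitters.
#' @param max_resample folds without any uncensored row are rejected and the
#'   assignment reseeded, at most this many times.
#' @return a `bj_cv` object: `lambdas`, `cv_mean`, `cv_se` (fold-level
#'   standard errors), `lambda_opt`, `fold_assignment`, `loss_type`,
#'   `method`, `loss_matrix`.
#' @export
cv_select_lambda <- function(ds, method = c("gaussbj", "gaussbj_1step",
                                            "nonparbj", "lod", "lod2"),
                             loss_type = c("imputed_sq", "gaussian"),
                             K = 5, seed = 1, n_lambda = 100,
                             lambda_min_ratio = 0.001, bj_opts = list(),
                             max_resample = 10) {
  method <- match.arg(method)
  loss_type <- match.arg(loss_type)
  grid <- suppressWarnings(
    lambda_grid(ds$X, ds$z, n_lambda, lambda_min_ratio))

  folds <- NULL
  for (a in seq_len(max_resample)) {
    cand <- stratified_kfold(ds$delta, K, if (a == 1) seed
                             else child_seed(seed, a))
    ok <- all(vapply(seq_len(K), function(k) {
      sum(ds$delta[cand == k] == 1) >= 1 && sum(ds$delta[cand != k] == 1) >= 2
    }, logical(1)))
    if (ok) {
      if (a > 1)
        message("fold assignment reseeded ", a - 1,
                " time(s) to keep uncensored rows in every fold")
      folds <- cand
      break
    }
  }
  if (is.null(folds)) stop("could not build folds with uncensored rows in ",
                           max_resample, " attempts")

  L <- length(grid)
  loss <- matrix(NA_real_, K, L)
  for (k in seq_len(K)) {
    learn <- subset_censored(ds, folds != k)
    test <- subset_censored(ds, folds == k)
    ctx <- suppressWarnings(design_context(learn$X, TRUE))
    path <- fit_path(learn, method, grid, ctx, bj_opts)
    loss[k, ] <- path_losses(path, learn, test, method, loss_type)
  }
  cv_mean <- colMeans(loss)
  cv_se <- apply(loss, 2, stats::sd) / sqrt(K)
  opt <- which.min(cv_mean)
  structure(list(lambdas = grid, cv_mean = cv_mean, cv_se = cv_se,
                 lambda_opt = grid[opt], fold_assignment = folds,
                 loss_type = loss_type, method = method,
                 loss_matrix = loss),
            class = "bj_cv")
}

#' @export
print.bj_cv <- function(x, ...) {
  cat(sprintf("bj_cv: method = %s, loss = %s, %d-fold\n", x$method,
              x$loss_type, max(x$fold_assignment)))
  cat(sprintf("  lambda_opt = %.4g (cv loss %.4g)\n", x$lambda_opt,
              min(x$cv_mean)))
  invisible(x)
}

#' Cross-validate and refit on the full data
#'
#' Convenience wrapper: [cv_select_lambda()] followed by the final fit of
#' the same method at the selected penalty on all rows.
#'
#' @inheritParams cv_select_lambda
#' @return list with elements `cv` (a `bj_cv`) and `fit` (a `bj_fit`).
#' @export
bjlasso_fit <- function(ds, method = "gaussbj", loss_type = "imputed_sq",
                        K = 5, seed = 1, n_lambda = 100,
                        lambda_min_ratio = 0.001, bj_opts = list()) {
  cv <- cv_select_lambda(ds, method, loss_type, K, seed, n_lambda,
                         lambda_min_ratio, bj_opts)
  fit <- fit_method(ds, method, cv$lambda_opt, bj_opts = bj_opts)
  list(cv = cv, fit = fit)
}
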
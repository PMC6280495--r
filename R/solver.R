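# Internal constructor for fitted-model objects. `beta` is always on the
# original predictor scale; `beta_std` (standardized scale) is kept for warm
# starts and convergence diagnostics.
new_bj_fit <- function(beta, intercept, sigma2 = NULL, lambda = 0,
                       n_iter = 1L, status = "direct", trace = NULL,
                       beta_std = NULL, names = NULL) {
  if (!is.null(names)) names(beta) <- names
  structure(list(beta = beta, intercept = intercept, sigma2 = sigma2,
                 lambda = lambda, n_iter = as.integer(n_iter),
                 status = status, trace = trace, beta_std = beta_std),
            class = "bj_fit")
}

#' @export
print.bj_fit <- function(x, ...) {
  cat(sprintf("bj_fit: status = %s, lambda = %.4g, iterations = %d\n",
              x$status, x$lambda, x$n_iter))
  cat(sprintf("  intercept = %.4g, nonzero coefficients = %d / %d\n",
              x$intercept, sum(x$beta != 0), length(x$beta)))
  if (!is.null(x$sigma2)) cat(sprintf("  sigma2 = %.4g\n", x$sigma2))
  invisible(x)
}

#' @export
coef.bj_fit <- function(object, ...) c(`(Intercept)` = object$intercept,
                                       object$beta)

#' Predict from a fitted model
#'
#' @param object a `bj_fit`.
#' @param X predictor matrix on the original scale.
#' @param ... unused.
#' @return linear predictor `intercept + X beta`.
#' @export
predict.bj_fit <- function(object, X, ...)
  as.numeric(object$intercept + as.matrix(X) %*% object$beta)

# Centered (and optionally standardized) design context with its Gram
# matrix, computed once and reused across many single-lambda fits.
design_context <- function(X, standardize = TRUE) {
  X <- as.matrix(X)
  if (standardize) {
    sd_ <- standardize_predictors(X)
    Xw <- sd_$X
    out <- list(Xw = Xw, centers = sd_$centers, scales = sd_$scales,
                keep = sd_$keep, names = colnames(X), standardize = TRUE)
  } else {
    centers <- colMeans(X)
    Xw <- sweep(X, 2, centers, "-")
    out <- list(Xw = Xw, centers = centers, scales = rep(1, ncol(X)),
                keep = rep(TRUE, ncol(X)), names = colnames(X),
                standardize = FALSE)
  }
  out$G <- crossprod(Xw)
  out
}

# Single-lambda L1 solve within a design context (feature-sign search with
# coordinate-descent fallback). Returns the working-scale coefficients plus
# the original-scale fit.
cd_solve <- function(ctx, y, lambda, beta_init = NULL, tol = 1e-9) {
  my <- mean(y)
  if (is.null(beta_init)) beta_init <- numeric(ncol(ctx$Xw))
  cvec <- crossprod(ctx$Xw, y - my)
  bw <- as.numeric(fss_lasso(ctx$G, cvec, lambda, beta_init, cd_tol = tol))
  p_all <- length(ctx$keep)
  beta <- numeric(p_all)
  beta[ctx$keep] <- bw / ctx$scales
  intercept <- my - sum((bw / ctx$scales) * ctx$centers)
  list(beta = beta, intercept = intercept, beta_std = bw)
}

#' L1-penalized least squares (Lasso)
#'
#' Minimizes `||y - intercept - X beta||_2^2 + lambda * ||beta||_1` — the
#' sum-of-squares scaling, with no `1/(2n)` factor. The intercept is fitted
#' but never penalized. The solver is feature-sign search: an active-set
#' method that alternates exact Karush-Kuhn-Tucker solves on the signed
#' active set with sign-consistency line searches, finishing in a finite
#' number of linear solves; a cyclic coordinate-descent fallback covers
#' numerically singular active sets. With `standardize = TRUE` (the default)
#' the penalty applies to coefficients of the internally standardized
#' predictors, and estimates are mapped back to the original scale; with
#' `standardize = FALSE` the stated objective is solved exactly on `X` as
#' given. Deterministic for fixed input.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param lambda penalty, `>= 0`.
#' @param standardize standardize columns internally (constant columns are
#'   dropped with a warning and get coefficient zero).
#' @param beta_init optional warm start on the working (standardized) scale.
#' @param tol convergence tolerance of the coordinate-descent fallback (max
#'   coefficient change per full pass).
#' @return a `bj_fit` with `status = "direct"`.
#' @examples
#' x <- matrix(c(1, -1, 1, -1), ncol = 1)
#' y <- c(1, 0, 1, 0)                    # t(x) %*% y = 2
#' lasso_fit(x, y, lambda = 2)$beta      # soft-threshold(2, 1) / 4 = 0.25
#' @export
lasso_fit <- function(X, y, lambda, standardize = TRUE, beta_init = NULL,
                      tol = 1e-9) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("dimension mismatch")
  if (lambda < 0) stop("lambda must be >= 0")
  ctx <- design_context(X, standardize)
  s <- cd_solve(ctx, y, lambda, beta_init, tol)
  new_bj_fit(s$beta, s$intercept, sigma2 = NULL, lambda = lambda,
             n_iter = 1L, status = "direct", beta_std = s$beta_std,
             names = colnames(X))
}

#' Ordinary least squares with intercept
#'
#' Standard QR-based least squares; the residual variance is recorded with
#' divisor `n - p - 1`.
#'
#' @param X predictor matrix, full column rank, `n > p + 1`.
#' @param y response vector.
#' @return a `bj_fit` with `sigma2` filled in.
#' @export
ols_fit <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("dimension mismatch")
  if (n <= p + 1) stop("need n > p + 1 for ordinary least squares")
  A <- cbind(`(Intercept)` = 1, X)
  qr_ <- qr(A)
  if (qr_$rank < ncol(A)) stop("rank-deficient design")
  cf <- qr.coef(qr_, y)
  res <- y - A %*% cf
  new_bj_fit(unname(cf[-1]), unname(cf[1]),
             sigma2 = sum(res^2) / (n - p - 1),
             lambda = 0, status = "direct", names = colnames(X))
}

#' Smallest penalty that zeroes every coefficient
#'
#' Under the sum-of-squares objective the Lasso solution is identically zero
#' iff `lambda >= 2 * max_j |x_j' (y - mean(y))|`, evaluated on the
#' (optionally standardized) design.
#'
#' @inheritParams lasso_fit
#' @return the critical penalty value.
#' @export
lambda_max <- function(X, y, standardize = TRUE) {
  ctx <- design_context(as.matrix(X), standardize)
  2 * max(abs(crossprod(ctx$Xw, y - mean(y))))
}

#' Log-spaced penalty grid
#'
#' Decreasing grid of `n_points` values from `lambda_max(X, y)` down to
#' `ratio` times it, equally spaced on the log scale — the standard path on
#' which cross-validation is evaluated.
#'
#' @inheritParams lasso_fit
#' @param n_points grid size (default 100).
#' @param ratio smallest-to-largest penalty ratio (default 0.001).
#' @return decreasing numeric vector of length `n_points`.
#' @export
lambda_grid <- function(X, y, n_points = 100, ratio = 0.001,
                        standardize = TRUE) {
  stopifnot(n_points >= 2, ratio > 0, ratio < 1)
  lmax <- lambda_max(X, y, standardize)
  if (lmax <= 0) return(rep(0, n_points))
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_points))
}
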
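# Observed-data Tobit negative log-likelihood (reference implementation;
# the C++ engine mirrors it for its best-iterate bookkeeping).
tobit_negloglik <- function(z, delta, lod, mu, sigma2) {
  sig <- sqrt(sigma2)
  unc <- delta == 1
  -(sum(stats::dnorm(z[unc], mu[unc], sig, log = TRUE)) +
      sum(stats::pnorm((lod[!unc] - mu[!unc]) / sig, log.p = TRUE)))
}

bj_statuses <- c("converged", "oscillated", "max_iter", "one_step")

# Map an engine result (standardized scale) back to the original predictor
# scale and package it as a bj_fit.
engine_to_fit <- function(res, ctx, lambda, names, trace_cols) {
  bw <- as.numeric(res$beta_std)
  beta <- numeric(length(ctx$keep))
  beta[ctx$keep] <- bw / ctx$scales
  intercept <- res$my - sum((bw / ctx$scales) * ctx$centers)
  tr <- res$trace
  colnames(tr) <- trace_cols
  fit <- new_bj_fit(beta, intercept, sigma2 = res$sigma2, lambda = lambda,
                    n_iter = res$n_iter, status = bj_statuses[res$status + 1],
                    trace = tr, beta_std = bw, names = names)
  fit$osc_count <- res$osc_count
  fit
}

#' Lasso fit after constant substitution of censored values
#'
#' The naive baseline: censored responses are replaced by the detection limit
#' (`divisor = 1`) or half of it (`divisor = 2`) and a plain Lasso is fitted.
#' Substituting the limit tends to overestimate the censored responses,
#' substituting half of it to underestimate them.
#'
#' @param ds a [censored_data()] object.
#' @param lambda L1 penalty.
#' @param divisor 1 (impute LOD) or 2 (impute LOD/2).
#' @return a `bj_fit` with `status = "direct"`.
#' @export
simple_imputation_fit <- function(ds, lambda, divisor = 1) {
  if (!divisor %in% c(1, 2)) stop("divisor must be 1 or 2")
  z <- ds$z
  cens <- ds$delta == 0
  z[cens] <- ds$lod[cens] / divisor
  lasso_fit(ds$X, z, lambda)
}

#' Gaussian Buckley-James Lasso fit
#'
#' Iterative estimator for the left-censored Gaussian linear model: alternate
#' between (i) imputing each censored response by its truncated-normal
#' conditional mean `E(Y | Y <= lod, X)` under the current fit, (ii) a Lasso
#' fit on the completed data, and (iii) an EM-style variance update that adds
#' the truncated conditional variances of the censored rows, so the noise
#' variance does not collapse when many imputations stack in the tail. At
#' `lambda = 0` the iteration is exactly EM for the Tobit model and converges
#' to the maximum-likelihood estimate; at `lambda > 0` it behaves as an
#' approximate penalized EM (the penalty weight is held at `lambda` rather
#' than rescaled by the current variance), so the penalized likelihood is
#' near-monotone but small late-stage fluctuations can occur — the stopping
#' machinery below absorbs them.
#'
#' The loop stops when coefficients, variance and imputed values all move
#' less than their tolerances (`status = "converged"`); when period-2 cycling
#' is detected `osc_limit` times (`status = "oscillated"`, returning the
#' visited iterate with the best penalized observed-data likelihood); or at
#' `max_iter` (`status = "max_iter"`, a non-convergent termination). With
#' `one_step = TRUE` exactly one imputation/fit pass is performed
#' (`status = "one_step"`), which equals the first iterate of the full loop.
#'
#' @param ds a [censored_data()] object with at least 2 uncensored rows.
#' @param lambda L1 penalty (sum-of-squares scaling).
#' @param max_iter maximum iterations (default 100).
#' @param tol_beta,tol_sigma,tol_impute stopping tolerances on the
#'   standardized-coefficient change, variance change and imputed-value
#'   change (defaults 1e-4).
#' @param osc_limit number of detected oscillation events before stopping.
#' @param one_step stop after the first iteration.
#' @param sigma_update `"em"` (default; conditional-variance augmented) or
#'   `"uncensored"` (residual variance on uncensored rows only), kept for
#'   sensitivity analysis.
#' @param beta_init optional warm start (standardized scale); defaults to the
#'   LOD-substitution Lasso fit.
#' @param ctx internal precomputed design context (used by cross-validation).
#' @return a `bj_fit` with `sigma2`, iteration `trace` and the final working
#'   responses in `$zstar`.
#' @export
gaussian_bj_fit <- function(ds, lambda, max_iter = 100, tol_beta = 1e-4,
                            tol_sigma = 1e-4, tol_impute = 1e-4,
                            osc_limit = 3, one_step = FALSE,
                            sigma_update = c("em", "uncensored"),
                            beta_init = NULL, ctx = NULL) {
  sigma_update <- match.arg(sigma_update)
  if (sum(ds$delta == 1) < 2) stop("need at least 2 uncensored observations")
  if (lambda < 0) stop("lambda must be >= 0")
  if (is.null(ctx)) ctx <- design_context(ds$X, TRUE)
  if (is.null(beta_init)) beta_init <- numeric(ncol(ctx$Xw))
  res <- gauss_bj_engine(ctx$Xw, ctx$G, ds$z, ds$delta, ds$lod, lambda,
                         beta_init, max_iter, tol_beta, tol_sigma,
                         tol_impute, osc_limit, one_step,
                         sigma_update == "em")
  fit <- engine_to_fit(res, ctx, lambda, colnames(ds$X),
                       c("iter", "d_beta", "d_sigma", "d_impute",
                         "objective"))
  fit$zstar <- as.numeric(res$zstar)
  fit
}

# Vectorized conditional mean over a km_curve for several thresholds, with
# the Buckley-James fallbacks: no mass strictly above c -> largest mass
# point (if not below c), else c itself.
km_cond_mean_vec <- function(curve, cvec) {
  tj <- curve$times
  cj <- curve$jumps
  k <- length(tj)
  tot_m <- cumsum(rev(cj))          # mass above, from the right
  tot_s <- cumsum(rev(cj * tj))
  idx <- findInterval(cvec, tj)     # number of times <= c
  above <- k - idx
  out <- numeric(length(cvec))
  ok <- above > 0
  out[ok] <- tot_s[above[ok]] / tot_m[above[ok]]
  if (any(!ok)) out[!ok] <- pmax(tj[k], cvec[!ok])
  out
}

#' Non-parametric (Kaplan-Meier) Buckley-James Lasso fit
#'
#' Distribution-free counterpart of [gaussian_bj_fit()]. The left-censored
#' data are flipped to right-censoring (`M - z`, with `M = max(z)`), and the
#' loop alternates between: computing flipped residuals under the current
#' fit, estimating their distribution by the tail-corrected Kaplan-Meier
#' product-limit estimator, imputing each censored residual by the KM
#' conditional mean above its own value, and refitting the Lasso on the
#' completed flipped responses. The residual mean is absorbed by the
#' unpenalized intercept at every iteration (the classical Buckley-James
#' intercept non-identifiability). Coefficients are mapped back by negation;
#' imputed responses on the original scale always lie below the detection
#' limit. Stopping and oscillation handling mirror [gaussian_bj_fit()]
#' (the returned iterate on oscillation is the one with the smallest
#' penalized uncensored-row squared error).
#'
#' @inheritParams gaussian_bj_fit
#' @return a `bj_fit` (no `sigma2`), with imputed original-scale responses in
#'   `$zstar` and the flip constant in `$M`.
#' @export
nonpar_bj_fit <- function(ds, lambda, max_iter = 100, tol_beta = 1e-4,
                          tol_impute = 1e-4, osc_limit = 3, one_step = FALSE,
                          beta_init = NULL, ctx = NULL) {
  if (sum(ds$delta == 1) < 2) stop("need at least 2 uncensored observations")
  if (lambda < 0) stop("lambda must be >= 0")
  fl <- flip_censoring(ds, "auto")
  if (is.null(ctx)) ctx <- design_context(ds$X, TRUE)
  if (is.null(beta_init)) beta_init <- numeric(ncol(ctx$Xw))
  res <- nonpar_bj_engine(ctx$Xw, ctx$G, fl$y_flip, ds$delta, lambda,
                          beta_init, max_iter, tol_beta, tol_impute,
                          osc_limit, one_step)
  # back-map from the flipped scale: negate coefficients, reflect the
  # centered mean through M so engine_to_fit reconstructs the left-scale
  # intercept
  res$beta_std <- -as.numeric(res$beta_std)
  res$my <- fl$M - res$my
  res$sigma2 <- NULL
  fit <- engine_to_fit(res, ctx, lambda, colnames(ds$X),
                       c("iter", "d_beta", "d_impute", "objective"))
  fit$zstar <- fl$M - as.numeric(res$ystar)
  fit$M <- fl$M
  fit
}
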
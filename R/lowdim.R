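#' Tobit maximum likelihood estimate
#'
#' Unpenalized maximum likelihood for the left-censored Gaussian linear
#' model: uncensored rows contribute the Gaussian density, censored rows the
#' probability of falling below their detection limit. Fitted through
#' [survival::survreg()] with a Gaussian distribution and left-censored
#' response, which maximizes exactly this log-likelihood. Intended for
#' low-dimensional illustration; it is not penalized.
#'
#' @param ds a [censored_data()] object with `n > p + 2` and at least two
#'   uncensored rows.
#' @param start optional starting coefficients `c(intercept, beta)`.
#' @return a `bj_fit` with `sigma2` (the squared scale), `status = "direct"`
#'   and the maximized log-likelihood in `$loglik`.
#' @export
tobit_mle <- function(ds, start = NULL) {
  n <- length(ds$z)
  p <- ncol(ds$X)
  if (n <= p + 2) stop("need n > p + 2")
  if (sum(ds$delta == 1) < 2) stop("need at least 2 uncensored observations")
  df <- data.frame(ds$X, check.names = FALSE)
  df$.z <- ds$z
  df$.d <- ds$delta
  fml <- stats::as.formula(paste(
    "survival::Surv(.z, .d, type = 'left') ~",
    paste(sprintf("`%s`", colnames(ds$X)), collapse = " + ")))
  sr <- survival::survreg(fml, data = df, dist = "gaussian",
                          init = start,
                          control = survival::survreg.control(
                            maxiter = 200, rel.tolerance = 1e-10))
  cf <- sr$coefficients
  fit <- new_bj_fit(unname(cf[-1]), unname(cf[1]), sigma2 = sr$scale^2,
                    lambda = 0, status = "direct", names = colnames(ds$X))
  fit$loglik <- sr$loglik[2]
  fit
}

# Mean absolute deviation objective with intercept.
lad_objective <- function(X, y, intercept, beta)
  mean(abs(y - intercept - as.numeric(X %*% beta)))

#' Least absolute deviations (median) regression
#'
#' Minimizes `(1/n) sum |y_i - intercept - X_i beta|`. An optimal LAD fit
#' interpolates `p + 1` observations, so for small problems the solution is
#' found exactly by enumerating all interpolating basic solutions; larger
#' problems fall back to iteratively reweighted least squares with a
#' smoothing floor, polished against the basic-solution property.
#'
#' @param X predictor matrix (`n > p`).
#' @param y response vector.
#' @param enumerate_limit maximum number of basic solutions to enumerate
#'   before switching to IRLS.
#' @return a `bj_fit` with `status = "direct"`.
#' @export
lad_fit <- function(X, y, enumerate_limit = 2e5) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("dimension mismatch")
  if (n <= p) stop("need n > p")
  A <- cbind(1, X)
  if (choose(n, p + 1) <= enumerate_limit) {
    combs <- utils::combn(n, p + 1)
    best <- NULL
    for (j in seq_len(ncol(combs))) {
      idx <- combs[, j]
      Aj <- A[idx, , drop = FALSE]
      qj <- qr(Aj)
      if (qj$rank < p + 1) next
      cf <- qr.coef(qj, y[idx])
      obj <- lad_objective(X, y, cf[1], cf[-1])
      if (is.null(best) || obj < best$obj - 1e-12)
        best <- list(cf = cf, obj = obj)
    }
    if (is.null(best)) stop("degenerate design: no full-rank basic solution")
    cf <- best$cf
  } else {
    cf <- qr.coef(qr(A), y)
    eps <- 1e-8
    for (it in 1:200) {
      r <- y - A %*% cf
      w <- 1 / pmax(abs(r), eps)
      cf_new <- qr.coef(qr(A * sqrt(w)), y * sqrt(w))
      if (max(abs(cf_new - cf)) < 1e-10) { cf <- cf_new; break }
      cf <- cf_new
    }
  }
  new_bj_fit(unname(cf[-1]), unname(cf[1]), lambda = 0, status = "direct",
             names = colnames(X))
}

#' Powell's censored least absolute deviations (CLAD) estimate
#'
#' Minimizes `(1/n) sum |z_i - max(lod_i, intercept + X_i beta)|` by the
#' iterative trimming scheme: keep the rows whose fitted value exceeds their
#' detection limit, refit LAD on them, and repeat until the kept set
#' stabilizes. A revisited set (cycle) stops the iteration and returns the
#' best-objective iterate.
#'
#' @param ds a [censored_data()] object.
#' @param max_iter maximum trimming iterations.
#' @return a `bj_fit` with `status` `"converged"` or `"max_iter"`, the final
#'   kept-row indicator in `$kept`, and the CLAD objective in `$objective`.
#' @export
clad_fit <- function(ds, max_iter = 50) {
  X <- ds$X
  n <- length(ds$z)
  clad_obj <- function(fit)
    mean(abs(ds$z - pmax(ds$lod, predict(fit, X))))
  fit <- lad_fit(X, ds$z)
  seen <- character()
  status <- "max_iter"
  best <- list(fit = fit, obj = clad_obj(fit), kept = rep(TRUE, n))
  for (t in seq_len(max_iter)) {
    keep <- predict(fit, X) > ds$lod
    if (!any(keep)) stop("trimming set became empty")
    key <- paste(which(keep), collapse = ",")
    fit_new <- lad_fit(X[keep, , drop = FALSE], ds$z[keep])
    obj <- clad_obj(fit_new)
    if (obj < best$obj - 1e-12)
      best <- list(fit = fit_new, obj = obj, kept = keep)
    if (key %in% seen) {        # cycle: keep the best iterate seen
      fit <- best$fit
      status <- "converged"
      break
    }
    seen <- c(seen, key)
    same <- max(abs(c(fit_new$intercept - fit$intercept,
                      fit_new$beta - fit$beta))) < 1e-12
    fit <- fit_new
    if (same) { status <- "converged"; break }
  }
  out <- new_bj_fit(fit$beta, fit$intercept, lambda = 0,
                    n_iter = 1L, status = status, names = colnames(X))
  out$objective <- clad_obj(fit)
  out$kept <- predict(fit, X) > ds$lod
  out
}

#' Side-by-side low-dimensional estimator comparison
#'
#' Fits the estimators used for the single-predictor illustration — gold
#' standard OLS on the latent response (simulated data only), Tobit maximum
#' likelihood, unpenalized Gaussian and non-parametric Buckley-James, LAD and
#' censored LAD, and the LOD / LOD/2 substitution OLS fits — and tabulates
#' intercepts and slopes.
#'
#' @param sd a `sim_data` object from [generate_lowdim_dataset()] (or any
#'   list with `ds` and optional `y_latent`).
#' @return data.frame with one row per method.
#' @export
lowdim_comparison <- function(sd) {
  ds <- sd$ds
  rows <- list()
  add <- function(method, fit)
    rows[[length(rows) + 1]] <<- data.frame(
      method = method, intercept = unname(fit$intercept),
      slope = unname(fit$beta[1]))
  if (!is.null(sd$beta_true))
    rows[[length(rows) + 1]] <- data.frame(
      method = "true", intercept = sd$beta0_true, slope = sd$beta_true[1])
  if (!is.null(sd$y_latent)) add("golds", ols_fit(ds$X, sd$y_latent))
  add("mle", tobit_mle(ds))
  add("gaussbj", gaussian_bj_fit(ds, lambda = 0))
  add("nonparbj", nonpar_bj_fit(ds, lambda = 0))
  add("lad", lad_fit(ds$X, ds$z))
  add("clad", clad_fit(ds))
  add("lod", ols_fit(ds$X, ds$z))
  z2 <- ds$z
  z2[ds$delta == 0] <- ds$lod[ds$delta == 0] / 2
  add("lod2", ols_fit(ds$X, z2))
  do.call(rbind, rows)
}
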
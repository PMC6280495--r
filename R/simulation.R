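#' Simulation configuration for the high-dimensional censored benchmark
#'
#' Parameters of the generator emulating a cross-sectional HIV viral-load
#' study: `n` patients, `p` binary mutation indicators with prevalence 0.15
#' and latent AR(1) correlation `rho^|i-j|`, a Gaussian baseline viral-load
#' covariate (mean 12 log10 copies/mL, variance 1) entering with slope
#' `beta1_baseline`, `n_relevant` mutations with effect `effect`, noise
#' variance set from the signal-to-noise ratio `snr` (variance of the full
#' linear predictor over the noise variance), and the intercept calibrated so
#' the Tobit censoring probability at `lod` matches `target_censoring`.
#'
#' @param n,p sample size and number of mutation predictors.
#' @param prevalence per-mutation prevalence.
#' @param rho latent AR(1) correlation base.
#' @param n_relevant number of truly associated mutations.
#' @param effect common effect size of the relevant mutations.
#' @param snr signal-to-noise ratio.
#' @param baseline_mean,baseline_var moments of the baseline covariate.
#' @param beta1_baseline slope of the baseline covariate.
#' @param target_censoring desired censoring probability in `[0, 1)`.
#' @param lod detection limit on the simulated scale.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n = 100, p = 100, prevalence = 0.15, rho = 0.4,
                       n_relevant = 10, effect = 1, snr = 3,
                       baseline_mean = 12, baseline_var = 1,
                       beta1_baseline = 0.5, target_censoring = 0.5,
                       lod = 1.0, seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1, rho >= 0, rho < 1, snr > 0,
            n_relevant <= p, target_censoring >= 0, target_censoring < 1)
  structure(list(n = n, p = p, prevalence = prevalence, rho = rho,
                 n_relevant = n_relevant, effect = effect, snr = snr,
                 baseline_mean = baseline_mean, baseline_var = baseline_var,
                 beta1_baseline = beta1_baseline,
                 target_censoring = target_censoring, lod = lod,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Correlated binary predictor matrix via a Gaussian copula
#'
#' Latent rows follow a standard Gaussian AR(1) process with correlation
#' `rho^|i-j|`; thresholding at the `1 - prevalence` quantile yields
#' Bernoulli(`prevalence`) columns whose dependence decays with the column
#' lag (neighbouring mutations are positively correlated). The induced
#' binary-scale correlation is smaller than the latent one.
#'
#' @param n,p dimensions.
#' @param prevalence marginal success probability.
#' @param rho latent AR(1) base, `0 <= rho < 1`.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return n x p 0/1 matrix.
#' @export
correlated_binary_matrix <- function(n, p, prevalence = 0.15, rho = 0.4,
                                     seed = NULL) {
  gen <- function() {
    L <- matrix(stats::rnorm(n * p), n, p)
    if (rho > 0 && p > 1) {
      w <- sqrt(1 - rho^2)
      for (j in 2:p) L[, j] <- rho * L[, j - 1] + w * L[, j]
    }
    (L > stats::qnorm(1 - prevalence)) * 1
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Calibrate intercept and noise variance of the simulation model
#'
#' On a large dedicated calibration sample the noise variance is set to
#' `Var(linear predictor) / snr`, and the intercept is found by monotone
#' root-finding so that the Tobit censoring probability
#' `P(Y <= lod) = E Phi((lod - beta0 - lp) / sigma)` matches the target
#' (within 0.005). A target of zero is resolved as a censoring probability
#' of 1e-4.
#'
#' @param config a [sim_config()].
#' @param calib_n calibration sample size (default 1e5).
#' @return list with `beta0`, `sigma2`, and the calibration-sample censoring
#'   probability `achieved`.
#' @export
calibrate_sim <- function(config, calib_n = 1e5) {
  cseed <- child_seed(config$seed, 999983L)
  lp <- with_seed(cseed, {
    y0 <- stats::rnorm(calib_n, config$baseline_mean,
                       sqrt(config$baseline_var))
    Xb <- if (config$n_relevant > 0) {
      Xm <- correlated_binary_matrix(calib_n, config$p, config$prevalence,
                                     config$rho)
      as.numeric(Xm[, seq_len(config$n_relevant), drop = FALSE] %*%
                   rep(config$effect, config$n_relevant))
    } else 0
    config$beta1_baseline * y0 + Xb
  })
  sigma2 <- stats::var(lp) / config$snr
  target <- max(config$target_censoring, 1e-4)
  sig <- sqrt(sigma2)
  prob <- function(b0) mean(stats::pnorm((config$lod - b0 - lp) / sig))
  span <- 10 * (sig + stats::sd(lp))
  lo <- config$lod - mean(lp) - span   # low intercept -> heavy censoring
  hi <- config$lod - mean(lp) + span
  if (prob(lo) < target || prob(hi) > target)
    stop("censoring target not bracketed; pathological configuration")
  beta0 <- stats::uniroot(function(b) prob(b) - target, c(lo, hi),
                          tol = 1e-6)$root
  list(beta0 = beta0, sigma2 = sigma2, achieved = prob(beta0))
}

#' Generate one simulated left-censored dataset
#'
#' Draws the baseline covariate, the correlated binary mutation matrix and
#' Gaussian noise, forms the latent response
#' `Y = beta0 + beta1_baseline * Y0 + X beta + e`, and applies the Tobit
#' observation rule at `lod`. The baseline covariate is included as the
#' first predictor column (`baseline`), so the fitted coefficient vector
#' spans `p + 1` entries.
#'
#' @param config a [sim_config()].
#' @param calibration optional precomputed [calibrate_sim()] result; when
#'   running many replicates calibrate once and pass it here.
#' @param seed overrides `config$seed` when given.
#' @return a `sim_data` list: `ds` ([censored_data()]), `y_latent`,
#'   `beta_true` (baseline slope first), `beta0_true`, `sigma2_true`,
#'   `achieved_censoring`, `config`.
#' @export
generate_sim_dataset <- function(config, calibration = NULL, seed = NULL) {
  if (is.null(calibration)) calibration <- calibrate_sim(config)
  if (is.null(seed)) seed <- config$seed
  out <- with_seed(seed, {
    y0 <- stats::rnorm(config$n, config$baseline_mean,
                       sqrt(config$baseline_var))
    Xm <- correlated_binary_matrix(config$n, config$p, config$prevalence,
                                   config$rho)
    eps <- stats::rnorm(config$n, 0, sqrt(calibration$sigma2))
    list(y0 = y0, Xm = Xm, eps = eps)
  })
  beta_mut <- c(rep(config$effect, config$n_relevant),
                rep(0, config$p - config$n_relevant))
  y_latent <- calibration$beta0 + config$beta1_baseline * out$y0 +
    as.numeric(out$Xm %*% beta_mut) + out$eps
  X <- cbind(baseline = out$y0, out$Xm)
  colnames(X) <- c("baseline", paste0("mut", seq_len(config$p)))
  delta <- as.numeric(y_latent > config$lod)
  z <- pmax(y_latent, config$lod)
  ds <- censored_data(z, delta, config$lod, X)
  structure(list(ds = ds, y_latent = y_latent,
                 beta_true = c(config$beta1_baseline, beta_mut),
                 beta0_true = calibration$beta0,
                 sigma2_true = calibration$sigma2,
                 achieved_censoring = mean(delta == 0),
                 config = config, seed = seed),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf(
    "sim_data: n = %d, p = %d predictors, censoring %.3f (target %.2f)\n",
    length(x$ds$z), ncol(x$ds$X), x$achieved_censoring,
    x$config$target_censoring))
  invisible(x)
}

#' Generate a single-predictor illustration dataset
#'
#' The low-dimensional setting used to contrast estimators graphically:
#' `Y = beta X + e` with `X ~ N(0,1)`, slope 10 by default and noise
#' variance `beta^2 / snr` (signal-to-noise 4:3 gives `sigma^2 = 75`). The
#' detection limit is placed at the theoretical `target_censoring` quantile
#' of the marginal response distribution.
#'
#' @param n sample size.
#' @param beta true slope.
#' @param snr signal-to-noise ratio.
#' @param target_censoring desired censoring rate in `[0, 1)`.
#' @param seed integer seed.
#' @return a `sim_data` list (see [generate_sim_dataset()]).
#' @export
generate_lowdim_dataset <- function(n, beta = 10, snr = 4 / 3,
                                    target_censoring = 0.5, seed = 1) {
  sigma2 <- beta^2 / snr
  out <- with_seed(seed, {
    x <- stats::rnorm(n)
    y <- beta * x + stats::rnorm(n, 0, sqrt(sigma2))
    list(x = x, y = y)
  })
  lod <- if (target_censoring > 0)
    stats::qnorm(target_censoring, 0, sqrt(beta^2 + sigma2))
  else min(out$y) - 1
  delta <- as.numeric(out$y > lod)
  z <- pmax(out$y, lod)
  ds <- censored_data(z, delta, lod, matrix(out$x, ncol = 1,
                                            dimnames = list(NULL, "x")))
  structure(list(ds = ds, y_latent = out$y, beta_true = beta,
                 beta0_true = 0, sigma2_true = sigma2,
                 achieved_censoring = mean(delta == 0),
                 config = list(n = n, beta = beta, snr = snr,
                               target_censoring = target_censoring,
                               lod = lod),
                 seed = seed),
            class = "sim_data")
}
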
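#' Conditional mean of a Gaussian below a threshold
#'
#' Computes `E(Y | Y <= c)` for `Y ~ Normal(mu, sigma^2)` through the closed
#' form `mu - sigma * phi(a) / Phi(a)` with `a = (c - mu) / sigma`. The
#' inverse Mills ratio is evaluated in log space
#' (`exp(log phi(a) - log Phi(a))`) so the result stays accurate when the
#' threshold sits far below the mean (severe censoring pushes many rows deep
#' into the lower tail). The result is always strictly below `c`.
#'
#' @param mu mean (vectorized).
#' @param sigma standard deviation, `> 0`.
#' @param c upper truncation point (vectorized).
#' @return `E(Y | Y <= c)`, same length as the recycled arguments.
#' @export
gaussian_conditional_mean <- function(mu, sigma, c) {
  if (any(!is.finite(mu)) || any(!is.finite(sigma)) || any(!is.finite(c)))
    stop("non-finite inputs")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  a <- (c - mu) / sigma
  h <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))
  mu - sigma * h
}

#' Conditional variance of a Gaussian below a threshold
#'
#' `Var(Y | Y <= c) = sigma^2 * (1 - a*h - h^2)` with `h = phi(a)/Phi(a)`,
#' `a = (c - mu)/sigma`. Lies in `(0, sigma^2]` and decays like
#' `sigma^2 / a^2` deep in the tail.
#'
#' @inheritParams gaussian_conditional_mean
#' @return the conditional variance.
#' @export
gaussian_conditional_var <- function(mu, sigma, c) {
  if (any(!is.finite(mu)) || any(!is.finite(sigma)) || any(!is.finite(c)))
    stop("non-finite inputs")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  a <- (c - mu) / sigma
  h <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))
  v <- sigma^2 * (1 - a * h - h^2)
  pmin(pmax(v, .Machine$double.xmin), sigma^2)
}

#' Kaplan-Meier product-limit estimate with tail correction
#'
#' Fits the product-limit survival estimator to a right-censored sample.
#' At tied values events precede censorings (the conventional rule). Any
#' residual survival mass beyond the last event — present whenever the
#' largest observation is censored — is reassigned to the largest observed
#' value, so the probability masses (`jumps`) always sum to one and
#' conditional means above any threshold with remaining mass are finite —
#' the standard Buckley-James practice.
#'
#' @param values numeric vector of (right-censored) observations.
#' @param events 0/1 vector, 1 = event (observed), 0 = censored.
#' @return a `km_curve` object: `times` (distinct mass locations, increasing),
#'   `surv` (survival just after each time), `jumps` (mass at each time).
#' @export
km_fit <- function(values, events) {
  if (!length(values)) stop("empty input")
  if (length(events) != length(values)) stop("dimension mismatch")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  events <- as.numeric(events)
  if (!any(events == 1)) stop("all observations censored")
  ut <- sort(unique(values))
  nrisk <- dcount <- numeric(length(ut))
  for (k in seq_along(ut)) {
    nrisk[k] <- sum(values >= ut[k])
    dcount[k] <- sum(values == ut[k] & events == 1)
  }
  ev <- dcount > 0
  S <- cumprod(1 - dcount / nrisk)
  Sprev <- c(1, S[-length(S)])
  times <- ut[ev]
  jumps <- (Sprev - S)[ev]
  # tail correction: residual mass beyond the last observation moves to the
  # largest observed value, so the jumps always sum to one
  tail_mass <- S[length(S)]
  if (tail_mass > 0) {
    vmax <- ut[length(ut)]
    if (length(times) && times[length(times)] == vmax) {
      jumps[length(jumps)] <- jumps[length(jumps)] + tail_mass
    } else {
      times <- c(times, vmax)
      jumps <- c(jumps, tail_mass)
    }
  }
  structure(list(times = times, surv = 1 - cumsum(jumps), jumps = jumps),
            class = "km_curve")
}

#' Conditional mean above a threshold under a Kaplan-Meier curve
#'
#' Discrete analogue of the conditional expectation
#' `E(T | T >= c) = sum_{t_k > c} jump_k t_k / S(c)` over the product-limit
#' jump set. Errors when no mass lies strictly above `c`; the Buckley-James
#' caller falls back to the largest mass point in that case.
#'
#' @param curve a `km_curve` from [km_fit()].
#' @param c threshold.
#' @return the conditional mean, always `> c`.
#' @export
km_conditional_mean <- function(curve, c) {
  keep <- curve$times > c
  S <- sum(curve$jumps[keep])
  if (S <= 0) stop("no support above threshold")
  sum(curve$jumps[keep] * curve$times[keep]) / S
}

#' Impute censored responses by truncated-Gaussian conditional means
#'
#' Leaves uncensored rows untouched and replaces each censored response by
#' `E(Y | Y <= lod_i, X_i)` under the Gaussian linear model with the supplied
#' coefficients and noise variance. Every imputed value lies strictly below
#' its row's detection limit.
#'
#' @param ds a [censored_data()] object.
#' @param beta coefficient vector on the original predictor scale.
#' @param intercept model intercept.
#' @param sigma2 noise variance, `> 0`.
#' @return numeric vector of working responses `z*`.
#' @export
impute_responses_gaussian <- function(ds, beta, intercept, sigma2) {
  mu <- as.numeric(intercept + ds$X %*% beta)
  zstar <- ds$z
  cens <- ds$delta == 0
  if (any(cens))
    zstar[cens] <- gaussian_conditional_mean(mu[cens], sqrt(sigma2),
                                             ds$lod[cens])
  zstar
}
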
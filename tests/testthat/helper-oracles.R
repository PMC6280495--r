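# Independent oracles used across the suite. These never call the package
# code paths they are checking.

# Truncated-normal conditional moments by adaptive quadrature of the
# defining integrals (numerator integrated, denominator from pnorm). The
# first-moment integrand changes sign at zero, so it is integrated piecewise
# to keep the adaptive routine's error control honest.
quad_first_moment <- function(a) {
  iq <- function(lo, hi) stats::integrate(function(t) t * stats::dnorm(t),
                                          lo, hi, rel.tol = 1e-13,
                                          abs.tol = 1e-300)$value
  if (a <= 0) iq(-40, a) else iq(-40, 0) + iq(0, a)
}

quad_trunc_mean <- function(mu, sigma, c) {
  a <- (c - mu) / sigma
  mu + sigma * quad_first_moment(a) / stats::pnorm(a)
}

quad_trunc_var <- function(mu, sigma, c) {
  a <- (c - mu) / sigma
  m1 <- quad_first_moment(a) / stats::pnorm(a)
  m2 <- stats::integrate(function(t) t^2 * stats::dnorm(t), -40, a,
                         rel.tol = 1e-13, abs.tol = 1e-300)$value /
    stats::pnorm(a)
  sigma^2 * (m2 - m1^2)
}

# Kaplan-Meier jump set via survival::survfit with the same tail correction
# (residual mass moved to the largest observation), then the conditional
# mean by direct enumeration over the jumps.
survfit_jumps <- function(values, events) {
  sf <- survival::survfit(survival::Surv(values, events) ~ 1)
  times <- sf$time[sf$n.event > 0]
  S <- sf$surv[sf$n.event > 0]
  jumps <- -diff(c(1, S))
  tail <- if (length(S)) S[length(S)] else 1
  if (tail > 1e-12) {
    vmax <- max(values)
    if (length(times) && abs(times[length(times)] - vmax) < 1e-12) {
      jumps[length(jumps)] <- jumps[length(jumps)] + tail
    } else {
      times <- c(times, vmax)
      jumps <- c(jumps, tail)
    }
  }
  list(times = times, jumps = jumps)
}

enum_km_cond_mean <- function(values, events, c) {
  js <- survfit_jumps(values, events)
  keep <- js$times > c
  if (!any(keep) || sum(js$jumps[keep]) <= 0) return(NA_real_)
  sum(js$jumps[keep] * js$times[keep]) / sum(js$jumps[keep])
}

# Exhaustive sign-pattern Lasso oracle for the sum-of-squares objective
# ||yc - Xc b||^2 + lambda ||b||_1 on centered data (p <= 3).
enum_lasso <- function(X, y, lambda) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  p <- ncol(X)
  obj <- function(b) sum((yc - Xc %*% b)^2) + lambda * sum(abs(b))
  best <- NULL
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (r in seq_len(nrow(signs))) {
    s <- signs[r, ]
    A <- which(s != 0)
    b <- numeric(p)
    if (length(A)) {
      XA <- Xc[, A, drop = FALSE]
      GA <- crossprod(XA)
      if (abs(det(GA)) < 1e-10) next
      bA <- solve(GA, crossprod(XA, yc) - (lambda / 2) * s[A])
      if (any(sign(bA) != s[A])) next
      b[A] <- bA
    }
    r_vec <- yc - Xc %*% b
    grad_ok <- all(abs(crossprod(Xc[, setdiff(seq_len(p), A), drop = FALSE],
                                 r_vec)) <= lambda / 2 + 1e-9)
    if (!grad_ok) next
    o <- obj(b)
    if (is.null(best) || o < best$obj) best <- list(b = b, obj = o)
  }
  best
}

# Small Tobit fixture: p = 1 left-censored Gaussian data.
make_tobit_ds <- function(n, beta = 2, sigma = 1, cens_q = 0.5, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    y <- beta * x + rnorm(n, 0, sigma)
    lod <- if (cens_q > 0) as.numeric(quantile(y, cens_q)) else min(y) - 1
    censored_data(pmax(y, lod), as.numeric(y > lod), lod,
                  matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  })
}
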
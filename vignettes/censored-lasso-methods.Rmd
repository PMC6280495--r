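---
title: "Penalized regression for detection-limited outcomes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized regression for detection-limited outcomes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative assays report a value only above their limit of detection
(LOD). HIV viral load is the motivating case: after a log10 transform the
concentration is well described by a Gaussian linear model, but any value at
or below the assay threshold is recorded only as "below LOD". Writing $Y_i$
for the latent response, $X_i$ for the $p$ predictors (typically 0/1
mutation indicators plus a baseline viral-load covariate) and
$\mathrm{LOD}_i$ for the per-subject threshold, the observation rule is the
Tobit model

$$Z_i = \max(Y_i, \mathrm{LOD}_i), \qquad
  \delta_i = \mathbb{I}(Y_i > \mathrm{LOD}_i), \qquad
  Y_i = \beta_0 + X_i\beta + \varepsilon_i,\;
  \varepsilon_i \sim N(0, \sigma^2).$$

With $p$ of the order of $n$ or larger, coefficients are estimated by the
Lasso,

$$\hat\beta(\lambda) \;=\; \arg\min_\beta\;
  \lVert Z^\* - X\beta\rVert_2^2 + \lambda \lVert\beta\rVert_1,$$

where $Z^\*$ is a working response in which censored entries have been
handled somehow. This package implements and compares the candidate
constructions of $Z^\*$:

* **Constant substitution** (`simple_imputation_fit()`): censored entries
  replaced by LOD or LOD/2. Cheap and biased — substitution by the limit
  overestimates the hidden values, substitution by half of it
  underestimates them.
* **Gaussian Buckley-James** (`gaussian_bj_fit()`): censored entries
  replaced by their truncated-normal conditional means
  $E(Y \mid Y \le \mathrm{LOD}, X) = \mu - \sigma\,\phi(a)/\Phi(a)$,
  $a = (\mathrm{LOD}-\mu)/\sigma$, under the current fit, alternating with
  the Lasso until the iteration stabilizes.
* **Non-parametric Buckley-James** (`nonpar_bj_fit()`): the data are
  flipped to right-censoring by subtracting from $M = \max_i Z_i$, residuals
  of the current fit are given a Kaplan-Meier distribution, and each
  censored residual is replaced by the KM conditional mean above its own
  value. No distributional assumption on $\varepsilon$.
* **Unpenalized baselines** (`tobit_mle()`, `lad_fit()`, `clad_fit()`):
  Tobit maximum likelihood, median regression, and Powell's censored median
  regression, for low-dimensional comparisons.

## The Gaussian Buckley-James iteration

One iteration does three things: (i) impute every censored response by its
truncated-normal conditional mean under the current $(\beta_0, \beta,
\sigma^2)$; (ii) refit the Lasso on the completed data (the intercept is
fitted but never penalized; predictors are standardized internally to zero
mean and unit population variance, and coefficients are reported back on
the original scale); (iii) update the variance by the EM rule

$$\sigma^2_{t+1} = \frac1n\Big[\sum_{\delta_i=1}(z_i-\hat\mu_i)^2 +
  \sum_{\delta_i=0}\big(v_i + (z^\*_i-\hat\mu_i)^2\big)\Big],$$

where $v_i$ is the truncated conditional variance evaluated at the
*previous* parameters and $\hat\mu_i$ the *new* linear predictor. This
makes the update the exact M-step of an EM algorithm: at $\lambda = 0$ the
iteration increases the observed-data Tobit likelihood monotonically and
converges to the maximum-likelihood estimate — which is why the
single-predictor Gaussian Buckley-James and the Tobit MLE coincide. With
$\lambda > 0$ the correspondence is only approximate (an exact penalized
M-step would rescale the penalty by $2\sigma^2$ each iteration, whereas the
estimator keeps the user's $\lambda$ fixed so that the penalized objective
matches the plain Lasso's), and small late-stage fluctuations of the
penalized likelihood can occur. An `"uncensored"` variance rule (residual
variance of the uncensored rows only) is retained behind the
`sigma_update` option for sensitivity analysis.

**Stopping.** The loop stops when the standardized coefficients, the
variance and the imputed values all move less than `tol_beta`,
`tol_sigma`, `tol_impute` (defaults `1e-4`, chosen to match the order of
cross-validation noise) — `status = "converged"`. Two safeguards cover
non-convergence: a period-2 cycling detector (an "oscillation event" is
$\lVert\beta_t-\beta_{t-2}\rVert_\infty < $ `tol_beta` while
$\lVert\beta_t-\beta_{t-1}\rVert_\infty \ge$ `tol_beta`; after `osc_limit
= 3` events the loop stops with `status = "oscillated"` and returns the
visited iterate with the best penalized observed-data likelihood), and an
iteration cap (`max_iter = 100`, `status = "max_iter"`). In practice, with
the inner Lasso solved exactly, we observe the EM-style iteration to be
smooth: runs that fail the tolerances within 100 iterations drift slowly
rather than cycle, so non-convergence essentially always surfaces as
`"max_iter"`. The `"oscillated"` machinery is retained because the
classical Buckley-James literature documents cycling for the
non-parametric variant, whose estimating function is piecewise linear.
`run_oscillation_experiment()` therefore reports the *non-convergent
termination* fraction (either safeguard) as its headline rate, with strict
cycling counted separately. Under the default tolerances this fraction
rises steeply with the censoring rate, though it remains below the rates
one obtains with tighter stopping rules — the quantity is highly sensitive
to those constants, for which no canonical values exist.

The `one_step = TRUE` variant performs exactly one imputation/refit pass —
the classical pragmatic answer to non-convergence — and equals the first
iterate of the full loop bit for bit.

**Initialization** is the LOD-substitution Lasso fit, with
$\sigma^2_0$ the mean squared residual of the uncensored rows; the loop
thus starts from the observed data rather than from zero.

## The non-parametric iteration

On the flipped scale ($M - Z$, right-censored at $M - \mathrm{LOD}$, with
$M = \max Z$, the smallest admissible flip constant), each iteration
computes residuals $e_i$ from the current fit, estimates their
distribution by the product-limit estimator (events before censorings at
ties), and replaces each censored residual by
$\sum_{t_k > e_i} j_k t_k / \sum_{t_k > e_i} j_k$ over the KM jumps. Any
survival mass remaining beyond the last event is reassigned to the largest
observed residual, so the jumps always sum to one and the conditional mean
exists whenever any mass lies above the threshold; a censored residual
above the whole support falls back to the largest mass point. The mean of
the imputed residuals is absorbed by the unpenalized intercept each
iteration — the classical Buckley-James intercept non-identifiability.
Coefficients map back by negation, the intercept by reflection through
$M$. Because the KM estimate is built from residuals pooled over subjects,
heterogeneous per-row detection limits are handled transparently (they
shift each row's censored residual, not the estimator itself).

## Choosing the penalty

`cv_select_lambda()` runs stratified K-fold cross-validation: censored and
uncensored indices are shuffled separately and dealt round-robin, so every
fold carries the study's censoring proportion to within one observation.
The penalty grid (100 points, log-spaced from $\lambda_{\max}$ — the
smallest penalty with all coefficients zero — down to $10^{-3}
\lambda_{\max}$) is shared by all folds, and the Buckley-James methods run
their full iterative loop at every grid value inside every fold,
warm-started from the previous grid point. Two held-out losses are
offered:

* `imputed_sq`: squared error with censored test values replaced by the
  conditional expectation estimated from the *learning* fold (Gaussian or
  KM, matching the method);
* `gaussian`: a censoring-aware likelihood loss,
  $\frac{1}{n_k^{\mathrm{unc}}}\sum_{\mathrm{unc}}(z_i-\hat\mu_i)^2 +
  \frac{2\hat\sigma^2}{n_k^{\mathrm{unc}}}
  \sum_{\mathrm{cens}}\big[-\ln\Phi\big((\mathrm{LOD}_i-\hat\mu_i)/
  \hat\sigma\big)\big]$,
  with $\hat\sigma^2$ from the learning fold (refreshed at every grid
  value, since each fit carries its own variance estimate). It reduces to
  the squared loss on uncensored folds, which keeps the two losses
  comparable.

The selected penalty minimizes the mean fold loss; ties break toward the
larger penalty (the sparser model). Folds that would contain no
uncensored observation are rejected and redealt (at most 10 reseedings).
K defaults to 5, matching the simulation design; 20 is the sensible choice
for sparse binary predictors on real cohorts, where more folds reduce the
chance of a test fold devoid of carriers of a rare mutation. For methods
that do not estimate a variance (substitution, non-parametric BJ) the
Gaussian loss, if requested, uses the uncensored-row residual variance — a
non-canonical combination accepted for completeness.

## The solver

The inner problem $\min_\beta \lVert y - \beta_0 - X\beta\rVert_2^2 +
\lambda\lVert\beta\rVert_1$ (sum-of-squares scaling throughout; wrappers
around solvers using the $1/2n$ convention would need
$\lambda_{\mathrm{internal}} = \lambda/(2n)$) is solved by feature-sign
search: an active-set method that alternates exact KKT solves on the
signed active set with sign-consistency line searches, finishing in a
finite number of Cholesky solves. The factor of the active-set Gram block
is cached and updated incrementally (forward-solve extension on
activation, Givens contraction on removal), which makes the thousands of
warm-started resolves inside a cross-validated Buckley-James run cheap. A
covariance-form cyclic coordinate descent (tolerance `1e-9` on the maximum
coefficient change per sweep) backstops numerically singular active sets.
Unit tests pin the solver against closed-form soft-thresholding, an
exhaustive sign-pattern oracle, and glmnet under the penalty mapping
above.

## The simulated benchmark

`generate_sim_dataset()` emulates a cross-sectional resistance study:
$n = 100$ patients, $p = 100$ binary mutation indicators with prevalence
0.15 and latent AR(1) Gaussian-copula correlation $0.4^{|i-j|}$
(thresholding makes the binary-scale correlation somewhat smaller than the
latent one — the binary-scale covariance is not directly realizable for
fixed Bernoulli margins), a Gaussian baseline covariate (mean 12 log10
copies/mL, variance 1) entering with slope 0.5, ten mutations with unit
effects, and noise variance set so that the signal-to-noise ratio —
defined as Var(linear predictor)/$\sigma^2$, including the baseline term —
equals 3. The intercept is calibrated by root-finding on a dedicated
$10^5$-row sample so the censoring probability at the fixed detection
limit (1.0 on the simulated scale; only the censoring probability is
identified, not the limit/intercept pair) hits the target rate of 20, 50
or 70%. Test sets are drawn with paired seeds and redrawn until their
censoring rate is within 0.05 of the training rate. The baseline covariate
is penalized like any other predictor by default. Prediction error is
measured against the *latent* response,
$\mathrm{MSE} = n_{\mathrm{test}}^{-1}\sum_i
(Y_i^{\mathrm{test}} - \hat\beta_0 - X_i^{\mathrm{test}}\hat\beta)^2$,
which is only possible on simulated data; `test_mse()` refuses real data
and points to the CV losses.

`run_mse_experiment()` (default 50 replicates per censoring level; the
printed study scale of 200 is a flag away) reproduces the qualitative
pattern: all methods sit near the uncensored gold standard at 20%
censoring, and at 50–70% the Gaussian Buckley-James leads, followed by the
non-parametric variant, with constant substitution last and increasingly
erratic. The single-predictor generator (`generate_lowdim_dataset()`,
slope 10, SNR 4:3 so $\sigma^2 = 75$, LOD at the marginal quantile of the
target rate) feeds `lowdim_comparison()` for the low-dimensional contrast
of all estimators.

What the generator does *not* emulate: linkage between specific mutation
pairs beyond AR(1) decay, non-Gaussian or heteroscedastic noise,
longitudinal structure, missing predictors, and per-subject detection
limits varying within one study (supported by the estimators, but the
generator uses a common limit). Passing benchmarks here therefore
demonstrate correctness of the machinery and the relative ordering of the
methods under the stated model, not performance on any particular cohort.

## Numerical choices and degenerate inputs

* Truncated-normal moments use the inverse Mills ratio in log space
  (`exp(log phi - log Phi)`), accurate to the quadrature oracle to 1e-8
  over $a \in [-8, 8]$ and stable far beyond; the conditional variance is
  clamped to $(0, \sigma^2]$.
* Constant predictor columns cannot be standardized; they are dropped with
  a warning and their coefficients reported as zero. Inside
  cross-validation the drop is silent (rare mutations routinely vanish
  from a learning fold).
* Censored rows must record their detection limit as the observed value;
  values within 1e-12 are snapped, anything further is an error.
* A fit requires at least two uncensored rows; the Gaussian loop aborts if
  the variance collapses below 1e-10.
* `lad_fit()` enumerates interpolating basic solutions exactly for small
  problems (the only regime the low-dimensional baselines target) and
  falls back to smoothed IRLS otherwise; `clad_fit()` stops when the
  trimming set repeats, returning the best-objective iterate on a cycle.
* All randomness (fold dealing, generators, experiment replication) flows
  through integer seeds derived from a single master seed, so every
  reported number is bit-reproducible.

## Known limitations

The oscillation-rate summary depends strongly on the stopping constants,
as discussed above. When the selected penalty leaves a large active set
relative to $n$, the completed-data fit can run close to interpolation
and the EM variance update then shrinks $\sigma^2$ steadily over the
iterations (the Tobit likelihood is unbounded in that regime); the
collapse guard aborts only below $10^{-10}$, so final fits at heavy
censoring may carry a small $\sigma^2$ — their linear predictors, which
drive prediction error, remain well behaved. The Gaussian loss assumes the learning-fold variance
transfers to the held-out fold. The non-parametric iteration inherits the
classical Buckley-James caveat that its fixed point is defined only up to
the intercept recentering. Standard errors for the penalized coefficients
are out of scope, as are ElasticNet/adaptive penalties and interval
censoring.
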
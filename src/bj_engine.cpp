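// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// L1 solver on the Gram form.
//
// Minimizes  f(b) = b'Gb - 2 c'b + lambda ||b||_1  (equivalently
// ||y - Xb||^2 + lambda ||b||_1 up to a constant, with G = X'X, c = X'y and
// X, y centered). Primary algorithm: feature-sign search (active-set with
// exact KKT solves and sign line-search), which terminates in a finite
// number of exact linear solves. Falls back to covariance-form cyclic
// coordinate descent if the active-set system is numerically singular or
// the step cap is hit.
// ---------------------------------------------------------------------------

// Covariance-form coordinate descent fallback (always correct, slower).
static void cd_gram(const arma::mat& G, const arma::vec& c, double lambda,
                    arma::vec& beta, double tol, int max_pass) {
  const int p = G.n_cols;
  const double half = lambda / 2.0;
  arma::vec gb = G * beta;                 // running G %*% beta
  for (int pass = 0; pass < max_pass; ++pass) {
    double maxdel = 0.0;
    for (int j = 0; j < p; ++j) {
      const double gjj = G(j, j);
      if (gjj <= 0.0) { beta[j] = 0.0; continue; }
      double u = c[j] - (gb[j] - gjj * beta[j]);
      double bnew = 0.0;
      if (u > half) bnew = (u - half) / gjj;
      else if (u < -half) bnew = (u + half) / gjj;
      double del = bnew - beta[j];
      if (del != 0.0) {
        gb += del * G.col(j);
        beta[j] = bnew;
        if (std::fabs(del) > maxdel) maxdel = std::fabs(del);
      }
    }
    if (maxdel < tol) break;
  }
}

// Cholesky factor of the active-set Gram block, maintained incrementally:
// reused unchanged between warm-started resolves, extended by a forward
// solve when one coordinate activates, and contracted by Givens rotations
// when one deactivates. A full refactorization backstops numerical
// degradation. The stored order is insertion order; lookups compare sets.
struct FssCache {
  std::vector<int> A;     // insertion order
  arma::mat R;            // upper-triangular, G_AA = R'R in that order
  bool valid = false;
  int mods = 0;           // incremental updates since last full factor
};

static bool full_factor(const arma::mat& G, FssCache& cache,
                        const std::vector<int>& A) {
  const int m = (int)A.size();
  arma::uvec Ai(m);
  for (int k = 0; k < m; ++k) Ai[k] = A[k];
  arma::mat GAA = G.submat(Ai, Ai);
  if (!arma::chol(cache.R, GAA)) { cache.valid = false; return false; }
  cache.A = A;
  cache.valid = true;
  cache.mods = 0;
  return true;
}

// Append index j to the factored set: G_AA,j column solve.
static bool factor_append(const arma::mat& G, FssCache& cache, int j) {
  const int m = (int)cache.A.size();
  if (m == 0) {
    if (G(j, j) <= 0.0) return false;
    cache.R.set_size(1, 1);
    cache.R(0, 0) = std::sqrt(G(j, j));
    cache.A.assign(1, j);
    cache.valid = true;
    return true;
  }
  arma::vec g(m);
  for (int k = 0; k < m; ++k) g[k] = G(cache.A[k], j);
  arma::vec r = arma::solve(arma::trimatl(cache.R.t()), g);
  double d2 = G(j, j) - arma::dot(r, r);
  if (d2 <= 1e-12 * std::max(1.0, G(j, j))) return false;
  arma::mat Rn(m + 1, m + 1, arma::fill::zeros);
  Rn.submat(0, 0, m - 1, m - 1) = cache.R;
  Rn.submat(0, m, m - 1, m) = r;
  Rn(m, m) = std::sqrt(d2);
  cache.R = std::move(Rn);
  cache.A.push_back(j);
  ++cache.mods;
  return true;
}

// Remove the set member at position k by Givens rotations.
static void factor_delete(FssCache& cache, int k) {
  const int m = (int)cache.A.size();
  cache.R.shed_col(k);
  for (int i = k; i < m - 1; ++i) {
    double a = cache.R(i, i), b = cache.R(i + 1, i);
    if (b != 0.0) {
      double rho = std::hypot(a, b);
      double cth = a / rho, sth = b / rho;
      for (int col = i; col < m - 1; ++col) {
        double x = cache.R(i, col), y = cache.R(i + 1, col);
        cache.R(i, col) = cth * x + sth * y;
        cache.R(i + 1, col) = -sth * x + cth * y;
      }
    }
  }
  cache.R.shed_row(m - 1);
  cache.A.erase(cache.A.begin() + k);
  ++cache.mods;
}

static bool cache_factor(const arma::mat& G, FssCache& cache,
                         const std::vector<int>& A) {
  if (cache.valid && cache.mods < 200 && A.size() == cache.A.size()) {
    if (A == cache.A) return true;
    std::vector<int> a1 = A, a2 = cache.A;
    std::sort(a1.begin(), a1.end());
    std::sort(a2.begin(), a2.end());
    if (a1 == a2) return true;   // same set, reuse stored order
  }
  return full_factor(G, cache, A);
}

// Feature-sign search. Returns false if it could not finish exactly (caller
// falls back to coordinate descent). The active set and its factor live in
// `cache` (insertion order), surviving across calls.
static bool fss_core(const arma::mat& G, const arma::vec& c, double lambda,
                     arma::vec& beta, FssCache& cache) {
  const int p = G.n_cols;
  const double half = lambda / 2.0;
  const double ktol = 1e-9 * std::max(1.0, half);
  std::vector<int> A0;
  A0.reserve(p);
  arma::vec s(p, arma::fill::zeros);
  for (int j = 0; j < p; ++j)
    if (beta[j] != 0.0) { A0.push_back(j); s[j] = (beta[j] > 0) ? 1.0 : -1.0; }
  if (A0.empty()) {
    cache.A.clear();
    cache.R.reset();
    cache.valid = true;
    cache.mods = 0;
  } else if (!cache_factor(G, cache, A0)) {
    return false;
  }

  const int max_steps = 6 * p + 60;
  for (int step = 0; step < max_steps; ++step) {
    if (cache.A.empty()) {
      // all-zero candidate: activate the worst KKT violator, if any
      arma::uword jmax;
      double vmax = arma::abs(c).max(jmax);
      if (vmax <= half + ktol) { beta.zeros(); return true; }
      if (!factor_append(G, cache, (int)jmax)) return false;
      s[jmax] = (c[jmax] > 0) ? 1.0 : -1.0;
      beta[jmax] = 0.0;
    }
    const std::vector<int>& A = cache.A;
    const int m = (int)A.size();
    arma::vec rhs(m), bold(m);
    for (int k = 0; k < m; ++k) {
      rhs[k] = c[A[k]] - half * s[A[k]];
      bold[k] = beta[A[k]];
    }
    arma::vec bnew = arma::solve(arma::trimatu(cache.R),
                                 arma::solve(arma::trimatl(cache.R.t()),
                                             rhs));
    if (!bnew.is_finite()) {
      if (!full_factor(G, cache, A)) return false;
      bnew = arma::solve(arma::trimatu(cache.R),
                         arma::solve(arma::trimatl(cache.R.t()), rhs));
      if (!bnew.is_finite()) return false;
    }

    // sign-consistency line search between bold and bnew
    bool consistent = true;
    for (int k = 0; k < m; ++k)
      if (bnew[k] * s[A[k]] <= 0.0) { consistent = false; break; }
    if (!consistent) {
      // candidate points: each zero crossing on the segment, plus bnew
      double best_obj = std::numeric_limits<double>::infinity();
      arma::vec best_b;
      arma::vec cA(m);
      arma::uvec Ai(m);
      for (int k = 0; k < m; ++k) { cA[k] = c[A[k]]; Ai[k] = A[k]; }
      arma::mat GA = G.submat(Ai, Ai);
      auto seg_obj = [&](const arma::vec& b) {
        return arma::as_scalar(b.t() * GA * b) - 2.0 * arma::dot(cA, b) +
          lambda * arma::norm(b, 1);
      };
      for (int k = 0; k < m; ++k) {
        if (bnew[k] * s[A[k]] > 0.0) continue;
        double denom = bold[k] - bnew[k];
        if (denom == 0.0) continue;
        double t = bold[k] / denom;
        if (t < 0.0 || t > 1.0) continue;
        arma::vec bt = bold + t * (bnew - bold);
        bt[k] = 0.0;
        double o = seg_obj(bt);
        if (o < best_obj) { best_obj = o; best_b = bt; }
      }
      double onew = seg_obj(bnew);
      if (onew < best_obj) { best_obj = onew; best_b = bnew; }
      if (!best_b.n_elem) return false;
      // write back; drop exact zeros from the set (factor downdates)
      for (int k = m - 1; k >= 0; --k) {
        beta[A[k]] = best_b[k];
        if (best_b[k] == 0.0) {
          s[A[k]] = 0.0;
          factor_delete(cache, k);
        } else {
          s[A[k]] = (best_b[k] > 0) ? 1.0 : -1.0;
        }
      }
      continue;
    }

    for (int k = 0; k < m; ++k) beta[A[k]] = bnew[k];
    // KKT check over inactive coordinates (beta is zero off the active set)
    arma::vec gfull = c - G * beta;
    int worst = -1;
    double vmax = half + ktol;
    for (int j = 0; j < p; ++j) {
      if (s[j] != 0.0) continue;
      double v = std::fabs(gfull[j]);
      if (v > vmax) { vmax = v; worst = j; }
    }
    if (worst < 0) return true;
    if (!factor_append(G, cache, worst)) {
      // singular extension: one full refactor attempt with the new set
      std::vector<int> Anew = A;
      Anew.push_back(worst);
      if (!full_factor(G, cache, Anew)) return false;
    }
    s[worst] = (gfull[worst] > 0) ? 1.0 : -1.0;
    beta[worst] = 0.0;
  }
  return false;
}

static void l1_solve(const arma::mat& G, const arma::vec& c, double lambda,
                     arma::vec& beta, FssCache& cache) {
  arma::vec init = beta;
  if (!fss_core(G, c, lambda, beta, cache)) {
    beta = init;
    cd_gram(G, c, lambda, beta, 1e-9, 200000);
  }
}

// [[Rcpp::export]]
arma::vec fss_lasso(const arma::mat& G, const arma::vec& c, double lambda,
                    const arma::vec& beta_init, double cd_tol = 1e-9,
                    int cd_max_pass = 200000) {
  arma::vec beta = beta_init;
  FssCache cache;
  if (!fss_core(G, c, lambda, beta, cache)) {
    beta = beta_init;
    cd_gram(G, c, lambda, beta, cd_tol, cd_max_pass);
  }
  return beta;
}

// ---------------------------------------------------------------------------
// Gaussian Buckley-James loop (standardized design; the R wrapper maps
// back). status codes: 0 converged, 1 oscillated, 2 max_iter, 3 one_step
// ---------------------------------------------------------------------------

static inline double gcm1(double mu, double sig, double lod) {
  double a = (lod - mu) / sig;
  double h = std::exp(R::dnorm(a, 0.0, 1.0, 1) - R::pnorm(a, 0.0, 1.0, 1, 1));
  return mu - sig * h;
}

static inline double gcv1(double mu, double sig, double lod, double s2) {
  double a = (lod - mu) / sig;
  double h = std::exp(R::dnorm(a, 0.0, 1.0, 1) - R::pnorm(a, 0.0, 1.0, 1, 1));
  double v = s2 * (1.0 - a * h - h * h);
  if (v < 1e-300) v = 1e-300;
  if (v > s2) v = s2;
  return v;
}

static double tobit_nll(const arma::vec& z, const arma::vec& mu,
                        const arma::uvec& unc, const arma::uvec& cen,
                        const arma::vec& lod, double s2) {
  double sig = std::sqrt(s2);
  double nll = 0.0;
  for (arma::uword k = 0; k < unc.n_elem; ++k) {
    arma::uword i = unc[k];
    nll -= R::dnorm(z[i], mu[i], sig, 1);
  }
  for (arma::uword k = 0; k < cen.n_elem; ++k) {
    arma::uword i = cen[k];
    nll -= R::pnorm((lod[i] - mu[i]) / sig, 0.0, 1.0, 1, 1);
  }
  return nll;
}

struct BjOpts {
  int max_iter;
  double tol_beta, tol_sigma, tol_impute;
  int osc_limit;
  bool one_step, sigma_em;
};

struct GaussResult {
  arma::vec beta, zstar;
  double my, sigma2;
  int status, n_iter, osc_count, best_iter;
  arma::mat trace;
};

static GaussResult gauss_bj_run(const arma::mat& Xw, const arma::mat& G,
                                const arma::vec& z, const arma::uvec& unc,
                                const arma::uvec& cen, const arma::vec& lod,
                                double lambda, const arma::vec& beta_init,
                                const BjOpts& o, FssCache& cache,
                                bool want_trace) {
  const int n = Xw.n_rows;
  double my0 = arma::mean(z);
  arma::vec beta = beta_init;
  arma::vec cvec = Xw.t() * (z - my0);
  l1_solve(G, cvec, lambda, beta, cache);
  arma::vec mu = Xw * beta + my0;
  double sigma2 = 0.0;
  for (arma::uword k = 0; k < unc.n_elem; ++k)
    sigma2 += std::pow(z[unc[k]] - mu[unc[k]], 2);
  sigma2 /= unc.n_elem;
  if (sigma2 < 1e-10) stop("sigma2 collapsed below 1e-10");

  GaussResult res;
  arma::vec beta_tm1 = beta, beta_tm2;
  arma::vec zstar_prev = z, zstar = z;
  double sigma2_prev = sigma2, my = my0;
  arma::vec mu_prev = mu;
  int osc_count = 0, status = 2, t_done = 0;
  if (want_trace) res.trace.set_size(o.max_iter, 5);
  double best_obj = std::numeric_limits<double>::infinity();
  arma::vec best_beta, best_zstar;
  double best_sigma2 = sigma2, best_my = my0;
  int best_iter = 0;

  for (int t = 1; t <= o.max_iter; ++t) {
    double sig = std::sqrt(sigma2_prev);
    zstar = z;
    double condvar_sum = 0.0;
    for (arma::uword k = 0; k < cen.n_elem; ++k) {
      arma::uword i = cen[k];
      zstar[i] = gcm1(mu_prev[i], sig, lod[i]);
      condvar_sum += gcv1(mu_prev[i], sig, lod[i], sigma2_prev);
    }
    my = arma::mean(zstar);
    cvec = Xw.t() * (zstar - my);
    beta = beta_tm1;
    l1_solve(G, cvec, lambda, beta, cache);
    mu = Xw * beta + my;

    double ss_unc = 0.0, ss_cen = 0.0;
    for (arma::uword k = 0; k < unc.n_elem; ++k)
      ss_unc += std::pow(z[unc[k]] - mu[unc[k]], 2);
    if (o.sigma_em) {
      for (arma::uword k = 0; k < cen.n_elem; ++k)
        ss_cen += std::pow(zstar[cen[k]] - mu[cen[k]], 2);
      sigma2 = (ss_unc + ss_cen + condvar_sum) / n;
    } else {
      sigma2 = ss_unc / unc.n_elem;
    }
    if (sigma2 < 1e-10) stop("sigma2 collapsed below 1e-10");

    double obj = tobit_nll(z, mu, unc, cen, lod, sigma2) +
      lambda * arma::norm(beta, 1);
    if (obj < best_obj) {
      best_obj = obj; best_beta = beta; best_zstar = zstar;
      best_sigma2 = sigma2; best_my = my; best_iter = t;
    }

    double d_beta = beta_tm1.n_elem ?
      arma::norm(beta - beta_tm1, "inf") : 0.0;
    double d_sigma = std::fabs(sigma2 - sigma2_prev);
    double d_imp = 0.0;
    for (arma::uword k = 0; k < cen.n_elem; ++k)
      d_imp = std::max(d_imp,
                       std::fabs(zstar[cen[k]] - zstar_prev[cen[k]]));
    if (want_trace)
      res.trace.row(t - 1) =
        arma::rowvec({(double)t, d_beta, d_sigma, d_imp, obj});
    t_done = t;

    if (o.one_step) { status = 3; break; }
    if (d_beta < o.tol_beta && d_sigma < o.tol_sigma &&
        d_imp < o.tol_impute) { status = 0; break; }
    if (t >= 2) {
      double d2 = arma::norm(beta - beta_tm2, "inf");
      if (d2 < o.tol_beta && d_beta >= o.tol_beta) {
        if (++osc_count >= o.osc_limit) { status = 1; break; }
      }
    }
    beta_tm2 = beta_tm1;
    beta_tm1 = beta;
    zstar_prev = zstar;
    sigma2_prev = sigma2;
    mu_prev = mu;
  }

  bool use_best = (status == 1);
  res.beta = use_best ? best_beta : beta;
  res.zstar = use_best ? best_zstar : zstar;
  res.my = use_best ? best_my : my;
  res.sigma2 = use_best ? best_sigma2 : sigma2;
  res.status = status;
  res.n_iter = t_done;
  res.osc_count = osc_count;
  res.best_iter = best_iter;
  if (want_trace && t_done > 0) res.trace.resize(t_done, 5);
  return res;
}

// [[Rcpp::export]]
List gauss_bj_engine(const arma::mat& Xw, const arma::mat& G,
                     const arma::vec& z, const arma::vec& delta,
                     const arma::vec& lod, double lambda,
                     const arma::vec& beta_init, int max_iter,
                     double tol_beta, double tol_sigma, double tol_impute,
                     int osc_limit, bool one_step, bool sigma_em) {
  arma::uvec unc = arma::find(delta == 1.0);
  arma::uvec cen = arma::find(delta == 0.0);
  BjOpts o{max_iter, tol_beta, tol_sigma, tol_impute, osc_limit, one_step,
           sigma_em};
  FssCache cache;
  GaussResult r = gauss_bj_run(Xw, G, z, unc, cen, lod, lambda, beta_init,
                               o, cache, true);
  return List::create(
    _["beta_std"] = r.beta, _["my"] = r.my, _["sigma2"] = r.sigma2,
    _["zstar"] = r.zstar, _["status"] = r.status, _["n_iter"] = r.n_iter,
    _["osc_count"] = r.osc_count, _["best_iter"] = r.best_iter,
    _["trace"] = r.trace);
}

// Whole-path variant used inside cross-validation: one call per fold runs
// the full Buckley-James loop at every penalty on the decreasing grid with
// warm starts, sharing the active-set factor cache.
// [[Rcpp::export]]
List gauss_bj_path_engine(const arma::mat& Xw, const arma::mat& G,
                          const arma::vec& z, const arma::vec& delta,
                          const arma::vec& lod, const arma::vec& lambdas,
                          int max_iter, double tol_beta, double tol_sigma,
                          double tol_impute, int osc_limit, bool one_step,
                          bool sigma_em) {
  arma::uvec unc = arma::find(delta == 1.0);
  arma::uvec cen = arma::find(delta == 0.0);
  BjOpts o{max_iter, tol_beta, tol_sigma, tol_impute, osc_limit, one_step,
           sigma_em};
  const int L = lambdas.n_elem, p = Xw.n_cols;
  arma::mat betas(p, L);
  arma::vec mys(L), sigma2s(L);
  arma::ivec statuses(L), n_iters(L);
  FssCache cache;
  arma::vec warm(p, arma::fill::zeros);
  for (int l = 0; l < L; ++l) {
    GaussResult r = gauss_bj_run(Xw, G, z, unc, cen, lod, lambdas[l], warm,
                                 o, cache, false);
    betas.col(l) = r.beta;
    mys[l] = r.my;
    sigma2s[l] = r.sigma2;
    statuses[l] = r.status;
    n_iters[l] = r.n_iter;
    warm = r.beta;
  }
  return List::create(_["beta_std"] = betas, _["my"] = mys,
                      _["sigma2"] = sigma2s, _["status"] = statuses,
                      _["n_iter"] = n_iters);
}

// ---------------------------------------------------------------------------
// Non-parametric (Kaplan-Meier) Buckley-James loop on flipped data.
// ---------------------------------------------------------------------------

// Product-limit jumps with events-before-censorings at ties and the
// largest-observation-as-event tail correction; then conditional means
// E(T | T > c) for each censored threshold via suffix sums.
static void km_impute(const arma::vec& e, const arma::vec& delta,
                      const arma::uvec& cen, arma::vec& estar) {
  const int n = e.n_elem;
  arma::uvec ord = arma::sort_index(e);
  std::vector<double> ut;
  std::vector<int> dcount, tcount;
  for (int k = 0; k < n; ++k) {
    double v = e[ord[k]];
    bool ev = delta[ord[k]] == 1.0;
    if (ut.empty() || v != ut.back()) {
      ut.push_back(v); dcount.push_back(ev ? 1 : 0); tcount.push_back(1);
    } else {
      if (ev) dcount.back() += 1;
      tcount.back() += 1;
    }
  }
  const int m = (int)ut.size();
  std::vector<double> jump(m, 0.0);
  double S = 1.0;
  int at_risk = n;
  for (int k = 0; k < m; ++k) {
    double Snew = S * (1.0 - (double)dcount[k] / at_risk);
    jump[k] = S - Snew;
    S = Snew;
    at_risk -= tcount[k];
  }
  // tail correction: residual mass moves to the largest observation
  if (S > 0.0) jump[m - 1] += S;
  std::vector<double> sm(m + 1, 0.0), st(m + 1, 0.0);
  for (int k = m - 1; k >= 0; --k) {
    sm[k] = sm[k + 1] + jump[k];
    st[k] = st[k + 1] + jump[k] * ut[k];
  }
  double tmax = ut.back();
  for (arma::uword q = 0; q < cen.n_elem; ++q) {
    double cth = e[cen[q]];
    int lo = (int)(std::upper_bound(ut.begin(), ut.end(), cth) - ut.begin());
    if (lo < m && sm[lo] > 0.0)
      estar[cen[q]] = st[lo] / sm[lo];
    else
      estar[cen[q]] = std::max(tmax, cth);
  }
}

struct NonparResult {
  arma::vec beta, ystar;
  double my;
  int status, n_iter, osc_count;
  arma::mat trace;
};

static NonparResult nonpar_bj_run(const arma::mat& Xw, const arma::mat& G,
                                  const arma::vec& yf,
                                  const arma::vec& delta,
                                  const arma::uvec& unc,
                                  const arma::uvec& cen, double lambda,
                                  const arma::vec& beta_init,
                                  const BjOpts& o, FssCache& cache,
                                  bool want_trace) {
  double my = arma::mean(yf);
  arma::vec beta = beta_init;
  arma::vec cvec = Xw.t() * (yf - my);
  l1_solve(G, cvec, lambda, beta, cache);

  NonparResult res;
  arma::vec beta_tm1 = beta, beta_tm2;
  arma::vec ystar = yf, ystar_prev = yf, estar(yf.n_elem);
  int osc_count = 0, status = 2, t_done = 0;
  if (want_trace) res.trace.set_size(o.max_iter, 4);
  double best_obj = std::numeric_limits<double>::infinity();
  arma::vec best_beta, best_ystar;
  double best_my = my;

  for (int t = 1; t <= o.max_iter; ++t) {
    arma::vec mu_f = Xw * beta_tm1 + my;
    arma::vec e = yf - mu_f;
    ystar = yf;
    if (cen.n_elem) {
      estar = e;
      km_impute(e, delta, cen, estar);
      for (arma::uword k = 0; k < cen.n_elem; ++k)
        ystar[cen[k]] = mu_f[cen[k]] + estar[cen[k]];
    }
    my = arma::mean(ystar);
    cvec = Xw.t() * (ystar - my);
    beta = beta_tm1;
    l1_solve(G, cvec, lambda, beta, cache);
    arma::vec mu_new = Xw * beta + my;

    double obj = lambda * arma::norm(beta, 1);
    for (arma::uword k = 0; k < unc.n_elem; ++k)
      obj += std::pow(yf[unc[k]] - mu_new[unc[k]], 2);
    if (obj < best_obj) {
      best_obj = obj; best_beta = beta; best_ystar = ystar; best_my = my;
    }

    double d_beta = arma::norm(beta - beta_tm1, "inf");
    double d_imp = 0.0;
    for (arma::uword k = 0; k < cen.n_elem; ++k)
      d_imp = std::max(d_imp,
                       std::fabs(ystar[cen[k]] - ystar_prev[cen[k]]));
    if (want_trace)
      res.trace.row(t - 1) = arma::rowvec({(double)t, d_beta, d_imp, obj});
    t_done = t;

    if (o.one_step) { status = 3; break; }
    if (d_beta < o.tol_beta && d_imp < o.tol_impute) { status = 0; break; }
    if (t >= 2) {
      double d2 = arma::norm(beta - beta_tm2, "inf");
      if (d2 < o.tol_beta && d_beta >= o.tol_beta) {
        if (++osc_count >= o.osc_limit) { status = 1; break; }
      }
    }
    beta_tm2 = beta_tm1;
    beta_tm1 = beta;
    ystar_prev = ystar;
  }

  bool use_best = (status == 1);
  res.beta = use_best ? best_beta : beta;
  res.ystar = use_best ? best_ystar : ystar;
  res.my = use_best ? best_my : my;
  res.status = status;
  res.n_iter = t_done;
  res.osc_count = osc_count;
  if (want_trace && t_done > 0) res.trace.resize(t_done, 4);
  return res;
}

// [[Rcpp::export]]
List nonpar_bj_engine(const arma::mat& Xw, const arma::mat& G,
                      const arma::vec& yf, const arma::vec& delta,
                      double lambda, const arma::vec& beta_init,
                      int max_iter, double tol_beta, double tol_impute,
                      int osc_limit, bool one_step) {
  arma::uvec unc = arma::find(delta == 1.0);
  arma::uvec cen = arma::find(delta == 0.0);
  BjOpts o{max_iter, tol_beta, 0.0, tol_impute, osc_limit, one_step, true};
  FssCache cache;
  NonparResult r = nonpar_bj_run(Xw, G, yf, delta, unc, cen, lambda,
                                 beta_init, o, cache, true);
  return List::create(
    _["beta_std"] = r.beta, _["my"] = r.my, _["ystar"] = r.ystar,
    _["status"] = r.status, _["n_iter"] = r.n_iter,
    _["osc_count"] = r.osc_count, _["trace"] = r.trace);
}

// [[Rcpp::export]]
List nonpar_bj_path_engine(const arma::mat& Xw, const arma::mat& G,
                           const arma::vec& yf, const arma::vec& delta,
                           const arma::vec& lambdas, int max_iter,
                           double tol_beta, double tol_impute,
                           int osc_limit, bool one_step) {
  arma::uvec unc = arma::find(delta == 1.0);
  arma::uvec cen = arma::find(delta == 0.0);
  BjOpts o{max_iter, tol_beta, 0.0, tol_impute, osc_limit, one_step, true};
  const int L = lambdas.n_elem, p = Xw.n_cols;
  arma::mat betas(p, L);
  arma::vec mys(L);
  arma::ivec statuses(L), n_iters(L);
  FssCache cache;
  arma::vec warm(p, arma::fill::zeros);
  for (int l = 0; l < L; ++l) {
    NonparResult r = nonpar_bj_run(Xw, G, yf, delta, unc, cen, lambdas[l],
                                   warm, o, cache, false);
    betas.col(l) = r.beta;
    mys[l] = r.my;
    statuses[l] = r.status;
    n_iters[l] = r.n_iter;
    warm = r.beta;
  }
  return List::create(_["beta_std"] = betas, _["my"] = mys,
                      _["status"] = statuses, _["n_iter"] = n_iters);
}

// Plain Lasso path on a fixed response (used for the substitution
// baselines inside cross-validation).
// [[Rcpp::export]]
arma::mat lasso_path_engine(const arma::mat& G, const arma::vec& cvec,
                            const arma::vec& lambdas) {
  const int L = lambdas.n_elem, p = G.n_cols;
  arma::mat betas(p, L);
  FssCache cache;
  arma::vec warm(p, arma::fill::zeros);
  for (int l = 0; l < L; ++l) {
    l1_solve(G, cvec, lambdas[l], warm, cache);
    betas.col(l) = warm;
  }
  return betas;
}
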
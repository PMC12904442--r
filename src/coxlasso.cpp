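#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Risk-set machinery for left-truncated right-censored Cox likelihoods with
// Breslow tie handling. A subject is at risk at event time t iff
// start < t <= stop. All quantities are computed per stratum and summed.
//
// For each stratum, with unique event times t_k (d_k events) and
// S_k = sum_{j at risk at t_k} w_j, w_j = exp(eta_j):
//   loglik = sum_events eta_i - sum_k d_k log S_k
//   A_i    = sum_{k : start_i < t_k <= stop_i} d_k / S_k
//   B_i    = sum_{k : start_i < t_k <= stop_i} d_k / S_k^2
//   grad_i = status_i - w_i A_i           (d loglik / d eta_i)
//   hess_i = w_i A_i - w_i^2 B_i          (diagonal of -d2 loglik / d eta^2)

struct StratumIndex {
  std::vector<int> idx;              // subject rows in this stratum
  std::vector<double> sorted_stop;   // ascending
  std::vector<int> order_stop;       // rows ordered by stop
  std::vector<double> sorted_start;  // ascending
  std::vector<int> order_start;      // rows ordered by start
  std::vector<double> etimes;        // unique event times ascending
  std::vector<double> dk;            // event counts per unique time
};

static std::vector<StratumIndex> build_strata(const NumericVector& start,
                                              const NumericVector& stop,
                                              const IntegerVector& status,
                                              const IntegerVector& strata,
                                              int nlev) {
  int n = start.size();
  std::vector<StratumIndex> out(nlev);
  for (int i = 0; i < n; ++i) out[strata[i]].idx.push_back(i);
  for (int s = 0; s < nlev; ++s) {
    StratumIndex& st = out[s];
    size_t m = st.idx.size();
    st.order_stop = st.idx;
    std::sort(st.order_stop.begin(), st.order_stop.end(),
              [&](int a, int b) { return stop[a] < stop[b]; });
    st.order_start = st.idx;
    std::sort(st.order_start.begin(), st.order_start.end(),
              [&](int a, int b) { return start[a] < start[b]; });
    st.sorted_stop.resize(m);
    st.sorted_start.resize(m);
    for (size_t i = 0; i < m; ++i) {
      st.sorted_stop[i] = stop[st.order_stop[i]];
      st.sorted_start[i] = start[st.order_start[i]];
    }
    // unique event times
    std::vector<double> ev;
    for (size_t i = 0; i < m; ++i)
      if (status[st.idx[i]] == 1) ev.push_back(stop[st.idx[i]]);
    std::sort(ev.begin(), ev.end());
    for (size_t i = 0; i < ev.size(); ++i) {
      if (i == 0 || ev[i] != ev[i - 1]) {
        st.etimes.push_back(ev[i]);
        st.dk.push_back(1.0);
      } else {
        st.dk.back() += 1.0;
      }
    }
  }
  return out;
}

// loglik, grad, hess at a given eta; eta is centred internally.
static double cox_quantities(const std::vector<StratumIndex>& strata,
                             const NumericVector& start,
                             const NumericVector& stop,
                             const IntegerVector& status,
                             const std::vector<double>& eta,
                             std::vector<double>& grad,
                             std::vector<double>& hess) {
  int n = start.size();
  double loglik = 0.0;
  std::fill(grad.begin(), grad.end(), 0.0);
  std::fill(hess.begin(), hess.end(), 0.0);

  for (size_t s = 0; s < strata.size(); ++s) {
    const StratumIndex& st = strata[s];
    size_t m = st.idx.size();
    size_t K = st.etimes.size();
    if (m == 0) continue;
    // centre eta within stratum for overflow safety
    double emax = -1e300;
    for (size_t i = 0; i < m; ++i) emax = std::max(emax, eta[st.idx[i]]);
    std::vector<double> w(m);
    // suffix sums of w over subjects sorted by stop / by start
    std::vector<double> suf_stop(m + 1, 0.0), suf_start(m + 1, 0.0);
    for (size_t i = 0; i < m; ++i) {
      double e = eta[st.order_stop[i]] - emax;
      w[i] = std::exp(std::max(-700.0, e));
    }
    for (int i = (int)m - 1; i >= 0; --i) suf_stop[i] = suf_stop[i + 1] + w[i];
    for (size_t i = 0; i < m; ++i) {
      double e = eta[st.order_start[i]] - emax;
      suf_start[i] = std::exp(std::max(-700.0, e));
    }
    {
      std::vector<double> tmp(m + 1, 0.0);
      for (int i = (int)m - 1; i >= 0; --i) tmp[i] = tmp[i + 1] + suf_start[i];
      for (size_t i = 0; i <= m; ++i) suf_start[i] = tmp[i];
    }
    // S_k for each unique event time: sum over stop >= t_k minus start >= t_k
    // G(t) = sum_{t_k <= t} d_k/S_k (prefix sums over event times), G2 with S^2
    std::vector<double> G(K + 1, 0.0), G2(K + 1, 0.0);
    for (size_t k = 0; k < K; ++k) {
      double t = st.etimes[k];
      // first index with sorted_stop >= t
      size_t a = std::lower_bound(st.sorted_stop.begin(), st.sorted_stop.end(), t) -
                 st.sorted_stop.begin();
      // first index with sorted_start >= t
      size_t b = std::lower_bound(st.sorted_start.begin(), st.sorted_start.end(), t) -
                 st.sorted_start.begin();
      double Sk = suf_stop[a] - suf_start[b];
      if (Sk <= 0) Rcpp::stop("empty risk set at event time %f", t);
      loglik -= st.dk[k] * (std::log(Sk) + emax);
      G[k + 1] = G[k] + st.dk[k] / Sk;
      G2[k + 1] = G2[k] + st.dk[k] / (Sk * Sk);
    }
    // accumulate per-subject A, B via G(stop_i) - G(start_i)
    for (size_t i = 0; i < m; ++i) {
      int row = st.idx[i];
      if (status[row] == 1) loglik += eta[row];
      // number of event times <= stop_i / <= start_i
      size_t ks = std::upper_bound(st.etimes.begin(), st.etimes.end(), stop[row]) -
                  st.etimes.begin();
      size_t ka = std::upper_bound(st.etimes.begin(), st.etimes.end(), start[row]) -
                  st.etimes.begin();
      double A = G[ks] - G[ka];
      double B = G2[ks] - G2[ka];
      double wi = std::exp(std::max(-700.0, std::min(700.0, eta[row] - emax)));
      // A, B were computed on the centred scale: S_k above absorbed exp(emax),
      // so d_k/S_k on the true scale is (d_k/S_k_centred) * exp(-emax); with
      // wi also centred the products wi*A, wi^2*B are scale-correct.
      grad[row] = (status[row] == 1 ? 1.0 : 0.0) - wi * A;
      hess[row] = wi * A - wi * wi * B;
    }
  }
  return loglik;
}

// [[Rcpp::export]]
List cpp_cox_quantities(NumericMatrix X, NumericVector beta,
                        NumericVector start, NumericVector stop,
                        IntegerVector status, IntegerVector strata,
                        int nstrata) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> eta(n, 0.0), grad(n), hess(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) eta[i] += X(i, j) * beta[j];
  std::vector<StratumIndex> st = build_strata(start, stop, status, strata, nstrata);
  double ll = cox_quantities(st, start, stop, status, eta, grad, hess);
  // gradient of -loglik/n wrt beta
  NumericVector gbeta(p);
  for (int j = 0; j < p; ++j) {
    double g = 0.0;
    for (int i = 0; i < n; ++i) g += X(i, j) * grad[i];
    gbeta[j] = -g / n;
  }
  return List::create(_["loglik"] = ll,
                      _["grad_eta"] = NumericVector(grad.begin(), grad.end()),
                      _["hess_eta"] = NumericVector(hess.begin(), hess.end()),
                      _["grad_beta"] = gbeta);
}

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// KKT violation on the exact partial-likelihood gradient (standardized scale)
static double kkt_violation(const NumericMatrix& X, const std::vector<double>& grad,
                            const std::vector<double>& beta, const NumericVector& pf,
                            double lambda) {
  int n = X.nrow(), p = X.ncol();
  double viol = 0.0;
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double g = 0.0;
    for (int i = 0; i < n; ++i) g += xj[i] * grad[i];
    g = -g / n; // d(-loglik/n)/d beta_j
    double thr = lambda * pf[j];
    double v;
    if (beta[j] != 0.0 || pf[j] == 0.0) {
      double s = beta[j] > 0 ? 1.0 : (beta[j] < 0 ? -1.0 : 0.0);
      v = (pf[j] == 0.0 && beta[j] == 0.0) ? std::fabs(g)
                                           : std::fabs(g + thr * s);
    } else {
      v = std::max(0.0, std::fabs(g) - thr);
    }
    viol = std::max(viol, v);
  }
  return viol;
}

// Pathwise lasso Cox with left-truncated risk sets.
// X must be standardized by the caller; pf are penalty factors (0 = unpenalized).
// [[Rcpp::export]]
List cpp_coxnet_path(NumericMatrix X, NumericVector start, NumericVector stop,
                     IntegerVector status, IntegerVector strata, int nstrata,
                     NumericVector pf, NumericVector lambda,
                     double tol, int maxit_outer, int maxit_inner,
                     double kkt_tol, bool early_stop) {
  int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix betas(p, L);
  NumericVector logliks(L), kkts(L);
  IntegerVector iters(L), sweeps(L);

  std::vector<StratumIndex> st = build_strata(start, stop, status, strata, nstrata);
  // saturated Breslow partial log-likelihood (ties only): -sum d_k log d_k
  double lsat = 0.0, nevents = 0.0;
  for (size_t s = 0; s < st.size(); ++s)
    for (size_t k = 0; k < st[s].dk.size(); ++k) {
      lsat -= st[s].dk[k] * std::log(st[s].dk[k]);
      nevents += st[s].dk[k];
    }
  std::vector<double> beta(p, 0.0), eta(n, 0.0), grad(n), hess(n), r(n), h(n);
  std::vector<double> denom(p), beta_start(p), beta2(p), eta2(n), g2(n), h2(n);
  std::vector<char> active(p, 0);
  auto pen_obj = [&](const std::vector<double>& b, double lam, double ll) {
    double pen = 0.0;
    for (int j = 0; j < p; ++j) pen += pf[j] * std::fabs(b[j]);
    return -ll / n + lam * pen;
  };
  auto eta_of = [&](const std::vector<double>& b, std::vector<double>& e) {
    std::fill(e.begin(), e.end(), 0.0);
    for (int j = 0; j < p; ++j) {
      if (b[j] == 0.0) continue;
      const double* xj = &X(0, j);
      for (int i = 0; i < n; ++i) e[i] += xj[i] * b[j];
    }
  };

  bool have_quants = false; // grad/hess/ll already valid for current beta
  double ll_cached = 0.0;
  for (int l = 0; l < L; ++l) {
    double lam = lambda[l];
    double ll = 0.0, viol = 1e300;
    int outer;
    for (outer = 0; outer < maxit_outer; ++outer) {
      if (have_quants) {
        ll = ll_cached;
        have_quants = false;
      } else {
        eta_of(beta, eta);
        ll = cox_quantities(st, start, stop, status, eta, grad, hess);
      }
      viol = kkt_violation(X, grad, beta, pf, lam);
      if (viol < kkt_tol) break;
      // solve the quadratic subproblem only as precisely as the current
      // outer accuracy warrants; tightens as the KKT violation shrinks
      double inner_tol = std::max(tol, 0.01 * viol);
      beta_start = beta;
      // quadratic approximation: weights h, residual r = grad/h
      for (int i = 0; i < n; ++i) {
        h[i] = std::max(hess[i], 1e-9);
        r[i] = grad[i] / h[i];
      }
      for (int j = 0; j < p; ++j) {
        const double* xj = &X(0, j);
        double d = 0.0;
        for (int i = 0; i < n; ++i) d += h[i] * xj[i] * xj[i];
        denom[j] = d / n;
        active[j] = (beta[j] != 0.0 || pf[j] == 0.0) ? 1 : 0;
      }
      // coordinate descent: full sweeps to grow the active set, then
      // active-set sweeps to convergence
      bool full_sweep = true;
      for (int it = 0; it < maxit_inner; ++it) {
        ++sweeps[l];
        double maxd = 0.0;
        bool grew = false;
        for (int j = 0; j < p; ++j) {
          if (!full_sweep && !active[j]) continue;
          if (denom[j] <= 1e-12) continue;
          const double* xj = &X(0, j);
          double num = 0.0;
          for (int i = 0; i < n; ++i) num += h[i] * xj[i] * r[i];
          num = num / n + denom[j] * beta[j];
          double bnew = soft_threshold(num, lam * pf[j]) / denom[j];
          double d = bnew - beta[j];
          if (d != 0.0) {
            for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
            beta[j] = bnew;
            maxd = std::max(maxd, std::fabs(d));
            if (!active[j]) { active[j] = 1; grew = true; }
          }
        }
        if (full_sweep) {
          full_sweep = false;
          if (maxd < inner_tol && !grew) break;
        } else if (maxd < inner_tol) {
          // verify with one more full sweep in the next iteration
          full_sweep = true;
        }
      }
      // the diagonal working Hessian over-estimates curvature, so the IRLS
      // step is conservative; try doubling it and keep whichever has the
      // lower penalized objective
      {
        bool moved = false;
        for (int j = 0; j < p; ++j) {
          beta2[j] = beta_start[j] + 2.0 * (beta[j] - beta_start[j]);
          if (beta2[j] != beta[j]) moved = true;
        }
        if (moved) {
          eta_of(beta, eta);
          double ll1 = cox_quantities(st, start, stop, status, eta, grad, hess);
          eta_of(beta2, eta2);
          double ll2 = cox_quantities(st, start, stop, status, eta2, g2, h2);
          if (pen_obj(beta2, lam, ll2) < pen_obj(beta, lam, ll1)) {
            beta = beta2;
            eta = eta2;
            grad = g2;
            hess = h2;
            ll_cached = ll2;
          } else {
            ll_cached = ll1;
          }
          have_quants = true; // both branches leave grad/hess/ll consistent
        }
      }
    }
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    logliks[l] = ll;
    kkts[l] = viol;
    iters[l] = outer;
    // early termination: (a) deviance ratio saturated or flat, or (b) the
    // model is no longer identifiable (as many selected features as
    // events). Remaining columns are padded so the grid stays aligned for
    // cross-validation; the caller truncates automatic paths
    if (early_stop && l >= 1) {
      bool bail = false;
      double denom0 = lsat - logliks[0];
      if (denom0 > 0) {
        double devr = (ll - logliks[0]) / denom0;
        double dprev = (logliks[l - 1] - logliks[0]) / denom0;
        bail = devr >= 0.99 || (l >= 2 && devr - dprev < 1e-5);
      }
      if (!bail) {
        int nnz = 0;
        for (int j = 0; j < p; ++j)
          if (beta[j] != 0.0 && pf[j] > 0.0) ++nnz;
        bail = nnz >= (int)nevents;
      }
      if (bail) {
        for (int l2 = l + 1; l2 < L; ++l2) {
          for (int j = 0; j < p; ++j) betas(j, l2) = beta[j];
          logliks[l2] = ll;
          kkts[l2] = NA_REAL;
          iters[l2] = 0;
        }
        return List::create(_["beta"] = betas, _["loglik"] = logliks,
                            _["kkt"] = kkts, _["iters"] = iters,
                            _["sweeps"] = sweeps, _["n_used"] = l + 1);
      }
    }
  }
  return List::create(_["beta"] = betas, _["loglik"] = logliks,
                      _["kkt"] = kkts, _["iters"] = iters,
                      _["sweeps"] = sweeps, _["n_used"] = L);
}

// Concordance with left-truncation-aware comparability:
// ordered pair (i, j) comparable iff status_i == 1 and
// entry_j < exit_i < exit_j; concordant when score_i > score_j, ties 1/2.
// [[Rcpp::export]]
List cpp_cindex(NumericVector entry, NumericVector exit, IntegerVector status,
                NumericVector score) {
  int n = entry.size();
  double conc = 0.0;
  long long comp = 0;
  for (int i = 0; i < n; ++i) {
    if (status[i] != 1) continue;
    double ti = exit[i], si = score[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (entry[j] < ti && ti < exit[j]) {
        ++comp;
        if (si > score[j]) conc += 1.0;
        else if (si == score[j]) conc += 0.5;
      }
    }
  }
  return List::create(_["concordant"] = conc, _["comparable"] = (double)comp);
}

// c-index for each column of a linear-predictor matrix (CV path scoring)
// [[Rcpp::export]]
NumericVector cpp_cindex_multi(NumericVector entry, NumericVector exit,
                               IntegerVector status, NumericMatrix lp) {
  int n = entry.size(), L = lp.ncol();
  NumericVector out(L);
  for (int l = 0; l < L; ++l) {
    double conc = 0.0;
    long long comp = 0;
    for (int i = 0; i < n; ++i) {
      if (status[i] != 1) continue;
      double ti = exit[i], si = lp(i, l);
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        if (entry[j] < ti && ti < exit[j]) {
          ++comp;
          if (si > lp(j, l)) conc += 1.0;
          else if (si == lp(j, l)) conc += 0.5;
        }
      }
    }
    out[l] = comp > 0 ? conc / comp : NA_REAL;
  }
  return out;
}
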
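#include <Rcpp.h>
using namespace Rcpp;

// log(exp(a) + exp(b)) without overflow
static inline double logadd(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// EM for a k-component exponential mixture, all densities in log space.
// Components whose weight or mean collapses below the guards are frozen out
// of the E step for the remainder of the run; latent-variable completion
// removes them afterwards (they end with n_j = 0).
// [[Rcpp::export]]
List cpp_em_fit(NumericVector tau, NumericVector pi0, NumericVector mu0,
                int max_iter, double tol) {
  const int n = tau.size(), k = pi0.size();
  std::vector<double> pi(pi0.begin(), pi0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<bool> frozen(k, false);
  double tau_min = *std::min_element(tau.begin(), tau.end());
  const double w_guard = 1e-12, mu_guard = 1e-12 * tau_min;

  std::vector<double> trace;
  trace.reserve(64);
  std::vector<double> gsum(k), gtsum(k), logp(k);
  double ll_prev = R_NegInf, ll = R_NegInf;
  int t = 0;

  for (t = 0; t < max_iter; ++t) {
    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gtsum.begin(), gtsum.end(), 0.0);
    std::vector<double> logpi(k), logmu(k), inv_mu(k);
    for (int j = 0; j < k; ++j) {
      logpi[j] = (frozen[j] || pi[j] <= 0.0) ? R_NegInf : std::log(pi[j]);
      logmu[j] = std::log(mu[j]);
      inv_mu[j] = 1.0 / mu[j];
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double lse = R_NegInf;
      for (int j = 0; j < k; ++j) {
        logp[j] = (logpi[j] == R_NegInf)
          ? R_NegInf : logpi[j] - logmu[j] - tau[i] * inv_mu[j];
        lse = logadd(lse, logp[j]);
      }
      ll += lse;
      for (int j = 0; j < k; ++j) {
        if (logp[j] == R_NegInf) continue;
        double g = std::exp(logp[j] - lse);
        gsum[j] += g;
        gtsum[j] += g * tau[i];
      }
    }
    trace.push_back(ll);
    // M step
    for (int j = 0; j < k; ++j) {
      if (frozen[j]) { pi[j] = 0.0; continue; }
      pi[j] = gsum[j] / n;
      if (gsum[j] > 0.0) mu[j] = gtsum[j] / gsum[j];
      if (pi[j] < w_guard || mu[j] < mu_guard) { frozen[j] = true; pi[j] = 0.0; }
    }
    // renormalise surviving weights (exact sum-to-one after freezing)
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += pi[j];
    for (int j = 0; j < k; ++j) pi[j] /= s;
    if (t > 0 && std::fabs(ll - ll_prev) < tol * std::fabs(ll_prev)) { ++t; break; }
    ll_prev = ll;
  }

  // marginal log-likelihood at the final parameter values
  double ll_final = 0.0;
  for (int i = 0; i < n; ++i) {
    double lse = R_NegInf;
    for (int j = 0; j < k; ++j) {
      if (frozen[j] || pi[j] <= 0.0) continue;
      lse = logadd(lse, std::log(pi[j]) - std::log(mu[j]) - tau[i] / mu[j]);
    }
    ll_final += lse;
  }

  return List::create(_["weights"] = NumericVector(pi.begin(), pi.end()),
                      _["means"] = NumericVector(mu.begin(), mu.end()),
                      _["loglik"] = ll_final,
                      _["iterations"] = t,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// Parametric complexity of the latent-completed exponential mixture,
// log C_EMM(n, k') for k' = 1..k, by the O(n^2 k) convolution recursion
//   C(n, k+1) = sum_{r1+r2=n} choose(n,r1) (r1/n)^r1 (r2/n)^r2 C(r1,k) C(r2,1)
// with conventions 0^0 = 1 and C(0, .) = 1, everything in log space.
// C(n, 1) = (n/e)^n * m_range / Gamma(n).
// [[Rcpp::export]]
NumericVector cpp_log_c_emm(int n, int k, double m_range) {
  std::vector<double> lgam(n + 2), lg(n + 1, 0.0);
  for (int i = 0; i <= n + 1; ++i) lgam[i] = std::lgamma((double) i + 1.0);
  for (int i = 1; i <= n; ++i) lg[i] = std::log((double) i);

  // L1[r] = log C(r, 1); L1[0] = 0
  std::vector<double> L1(n + 1, 0.0);
  for (int r = 1; r <= n; ++r)
    L1[r] = r * lg[r] - r - std::lgamma((double) r) + std::log(m_range);

  NumericVector out(k);
  out[0] = L1[n];
  if (k == 1) return out;

  std::vector<double> Lk(L1), Lnext(n + 1, 0.0);
  for (int kk = 2; kk <= k; ++kk) {
    Lnext[0] = 0.0;
    for (int r = 1; r <= n; ++r) {
      double acc = R_NegInf;
      for (int r1 = 0; r1 <= r; ++r1) {
        int r2 = r - r1;
        double term = lgam[r] - lgam[r1] - lgam[r2];
        if (r1 > 0) term += r1 * (lg[r1] - lg[r]);
        if (r2 > 0) term += r2 * (lg[r2] - lg[r]);
        term += Lk[r1] + L1[r2];
        acc = logadd(acc, term);
      }
      Lnext[r] = acc;
    }
    Lk.swap(Lnext);
    out[kk - 1] = Lk[n];
  }
  return out;
}
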
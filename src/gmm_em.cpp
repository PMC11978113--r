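#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// EM for a univariate Gaussian mixture. Pure deterministic iteration from
// the supplied start; collapse (vanishing component mass or sd) is
// reported back so the caller can restart from another seed.
// [[Rcpp::export(name = ".gmm_em_cpp")]]
List gmm_em_cpp(NumericVector x, NumericVector w0, NumericVector mu0,
                NumericVector sd0, double tol, int max_iter) {
  const int n = x.size(), K = w0.size();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sd(sd0.begin(), sd0.end());
  NumericVector trace(max_iter);
  NumericMatrix resp(n, K);
  const double LC = -0.5 * std::log(2.0 * M_PI);
  double ll_old = R_NegInf;
  int it = 0;
  bool collapsed = false;

  for (it = 0; it < max_iter; ++it) {
    // E-step with row-wise log-sum-exp
    double ll = 0.0;
    std::vector<double> lw(K), ls(K);
    for (int k = 0; k < K; ++k) {
      lw[k] = std::log(w[k]);
      ls[k] = std::log(sd[k]);
    }
    for (int j = 0; j < n; ++j) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double z = (x[j] - mu[k]) / sd[k];
        double lk = lw[k] - ls[k] + LC - 0.5 * z * z;
        resp(j, k) = lk;
        if (lk > mx) mx = lk;
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += std::exp(resp(j, k) - mx);
      double lse = mx + std::log(s);
      ll += lse;
      for (int k = 0; k < K; ++k) resp(j, k) = std::exp(resp(j, k) - lse);
    }
    trace[it] = ll;

    // M-step
    for (int k = 0; k < K; ++k) {
      double nk = 0.0, sx = 0.0;
      for (int j = 0; j < n; ++j) { nk += resp(j, k); sx += resp(j, k) * x[j]; }
      if (nk < 1e-8) { collapsed = true; break; }
      double m = sx / nk, sv = 0.0;
      for (int j = 0; j < n; ++j) {
        double d = x[j] - m;
        sv += resp(j, k) * d * d;
      }
      w[k] = nk / n;
      mu[k] = m;
      sd[k] = std::sqrt(sv / nk);
      if (sd[k] < 1e-6) { collapsed = true; break; }
    }
    if (collapsed) { ++it; break; }
    if (R_finite(ll_old) && (ll - ll_old) < tol * std::fabs(ll_old)) {
      ++it; break;
    }
    ll_old = ll;
  }
  if (it == 0) it = 1;
  if (it > max_iter) it = max_iter;
  return List::create(
    _["weights"] = NumericVector(w.begin(), w.end()),
    _["means"] = NumericVector(mu.begin(), mu.end()),
    _["sds"] = NumericVector(sd.begin(), sd.end()),
    _["ll_trace"] = trace[Range(0, it - 1)],
    _["n_iter"] = it,
    _["collapsed"] = collapsed);
}
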
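#include <Rcpp.h>
using namespace Rcpp;

// Fused in-place Adam update over a list of parameter arrays.
// params, m and v are owned by the training loop (deep-copied before
// training starts), so in-place mutation is safe.
// [[Rcpp::export(rng = false)]]
void adam_step_impl(List params, List grads, List m, List v,
                    double lr, double beta1, double beta2, double eps,
                    int t) {
  const double alpha =
      lr * std::sqrt(1.0 - std::pow(beta2, t)) / (1.0 - std::pow(beta1, t));
  const int np = params.size();
  for (int i = 0; i < np; ++i) {
    NumericVector p(params[i]), g(grads[i]), mm(m[i]), vv(v[i]);
    const R_xlen_t n = p.size();
    double *pp = REAL(p), *pg = REAL(g), *pm = REAL(mm), *pv = REAL(vv);
    for (R_xlen_t j = 0; j < n; ++j) {
      pm[j] = beta1 * pm[j] + (1.0 - beta1) * pg[j];
      pv[j] = beta2 * pv[j] + (1.0 - beta2) * pg[j] * pg[j];
      pp[j] -= alpha * pm[j] / (std::sqrt(pv[j]) + eps);
    }
  }
}
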
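#include <Rcpp.h>
using namespace Rcpp;

// One Adam step over a flat parameter vector, updating the parameter and
// both moment buffers in place (the training loop owns uniquely
// referenced, duplicated copies). The per-element arithmetic matches the
// reference elementwise formulation exactly:
//   m <- b1 * m + (1 - b1) * g
//   v <- b2 * v + (1 - b2) * g * g
//   theta <- theta - lr * (m / c1) / (sqrt(v / c2) + eps)
// with the bias corrections c1, c2 computed by the caller.
// [[Rcpp::export(rng = false)]]
void adam_update(NumericVector theta, NumericVector m, NumericVector v,
                 NumericVector g, double lr, double c1, double c2,
                 double b1, double b2, double eps) {
  R_xlen_t n = theta.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double mi = b1 * m[i] + (1 - b1) * g[i];
    double vi = b2 * v[i] + (1 - b2) * (g[i] * g[i]);
    m[i] = mi;
    v[i] = vi;
    theta[i] = theta[i] - lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
}
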
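#include <Rcpp.h>
using namespace Rcpp;

// Fused in-place Adam update: p -= lr * mhat / (sqrt(vhat) + eps), with the
// first/second-moment buffers updated in the same pass.  The R-level update
// would traverse multi-million-element weight matrices ~10 times per step;
// this keeps it to one pass.  c1 = 1/(1-beta1^t), c2 = 1/(1-beta2^t).
// [[Rcpp::export]]
void adam_update(NumericVector p, NumericVector m, NumericVector v,
                 NumericVector g, double lr, double beta1, double beta2,
                 double eps, double c1, double c2) {
  R_xlen_t n = p.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("adam_update: length mismatch");
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i];
    double mi = beta1 * m[i] + (1.0 - beta1) * gi;
    double vi = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    m[i] = mi;
    v[i] = vi;
    p[i] -= lr * (mi * c1) / (std::sqrt(vi * c2) + eps);
  }
}
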
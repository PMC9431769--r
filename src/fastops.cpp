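// Fused numeric kernels for the training loop.
//
// Both functions mutate their first argument in place; callers own the
// buffers (they are created inside the training loop and never shared
// with user-visible objects).

#include <Rcpp.h>
using namespace Rcpp;

// One Adam step over a parameter buffer: updates first/second moment
// estimates m, v and the parameter p in place.  c1, c2 are the bias
// corrections 1 - beta1^t and 1 - beta2^t.
// [[Rcpp::export(name = ".adamUpdate")]]
void adamUpdate(NumericVector p, NumericVector g, NumericVector m,
                NumericVector v, double lr, double b1, double b2,
                double c1, double c2, double eps) {
  R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1.0 - b1) * g[i];
    v[i] = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}

// target[idx] += val with 1-based indices; duplicates accumulate
// sequentially, so overlapping kernel footprints in col2im are safe.
// [[Rcpp::export(name = ".scatterAdd")]]
void scatterAdd(NumericVector target, IntegerVector idx,
                NumericVector val) {
  R_xlen_t n = idx.size();
  for (R_xlen_t i = 0; i < n; ++i)
    target[idx[i] - 1] += val[i];
}
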
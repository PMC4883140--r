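#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Mutual information (bits) between an integer reference vector and every
// column of an integer state matrix, via joint count tables. States must be
// small non-negative integers (the mRMR discretizer emits 0..2).
// [[Rcpp::export]]
NumericVector cpp_mi_columns(IntegerVector ref, IntegerMatrix states,
                             IntegerVector cols) {
  const int n = ref.size();
  int rmax = 0;
  for (int i = 0; i < n; ++i) if (ref[i] > rmax) rmax = ref[i];
  const int nr = rmax + 1;
  NumericVector out(cols.size());
  for (int c = 0; c < cols.size(); ++c) {
    const int j = cols[c];
    int smax = 0;
    for (int i = 0; i < n; ++i) if (states(i, j) > smax) smax = states(i, j);
    const int ns = smax + 1;
    std::vector<double> joint(nr * ns, 0.0), pr(nr, 0.0), ps(ns, 0.0);
    for (int i = 0; i < n; ++i) {
      joint[ref[i] * ns + states(i, j)] += 1.0;
      pr[ref[i]] += 1.0;
      ps[states(i, j)] += 1.0;
    }
    double mi = 0.0;
    for (int a = 0; a < nr; ++a)
      for (int b = 0; b < ns; ++b) {
        const double pj = joint[a * ns + b] / n;
        if (pj > 0.0)
          mi += pj * std::log2(pj * n * n / (pr[a] * ps[b]));
      }
    out[c] = mi;
  }
  return out;
}
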
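#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Nearest-centroid assignment under the L_q metric (q = 1 or 2) and the
// within-cluster objective: sum over points of ||x - b_assigned||_q^q.
// Ties are broken toward the lowest cluster index (strict '<' comparison).
// [[Rcpp::export(name = ".nearest_assignment_cpp")]]
List nearest_assignment_cpp(NumericMatrix X, NumericMatrix B, int q) {
  const int n = X.nrow(), d = X.ncol(), k = B.nrow();
  IntegerVector assign(n);
  NumericVector cost(n);
  double obj = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = X(i, c) - B(j, c);
        s += (q == 2) ? diff * diff : std::fabs(diff);
      }
      if (s < best) { best = s; bj = j; }
    }
    assign[i] = bj + 1;
    cost[i] = best;
    obj += best;
  }
  return List::create(_["assignment"] = assign,
                      _["objective"] = obj,
                      _["point_cost"] = cost);
}
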
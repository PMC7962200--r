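#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Horizontal visibility: nodes i < j are linked iff every intermediate sample
// is strictly below both endpoints. Single left-to-right sweep with a
// monotone stack; each node is pushed and popped at most once, so the whole
// scan is O(N) amortized. Ties: an intermediate equal to either endpoint
// blocks, but two equal-valued nodes with strictly lower samples between them
// are mutually visible; the equal node then blocks everything behind it.
// [[Rcpp::export]]
IntegerMatrix hvg_edges_cpp(NumericVector x) {
  int n = x.size();
  std::vector<int> from, to, stack;
  from.reserve(2 * n);
  to.reserve(2 * n);
  for (int j = 0; j < n; ++j) {
    while (!stack.empty()) {
      int i = stack.back();
      if (x[i] < x[j]) {
        from.push_back(i); to.push_back(j);
        stack.pop_back();
      } else {
        from.push_back(i); to.push_back(j);
        if (x[i] == x[j]) stack.pop_back();
        break;
      }
    }
    stack.push_back(j);
  }
  int m = from.size();
  IntegerMatrix edges(m, 2);
  for (int e = 0; e < m; ++e) {
    edges(e, 0) = from[e] + 1;
    edges(e, 1) = to[e] + 1;
  }
  return edges;
}

// Natural visibility: i < j are linked iff every intermediate sample lies
// strictly below the chord joining (i, x_i) and (j, x_j); an intermediate on
// the chord (within tol, compared on slopes) blocks. For each anchor i we
// track the running maximum slope to intermediates, so the scan is O(N^2).
// [[Rcpp::export]]
IntegerMatrix vg_edges_cpp(NumericVector x, double tol) {
  int n = x.size();
  std::vector<int> from, to;
  from.reserve(4 * n);
  to.reserve(4 * n);
  for (int i = 0; i < n - 1; ++i) {
    double maxslope = R_NegInf;
    for (int j = i + 1; j < n; ++j) {
      double slope = (x[j] - x[i]) / (double)(j - i);
      if (j == i + 1 || slope > maxslope + tol) {
        from.push_back(i + 1); to.push_back(j + 1);
      }
      if (slope > maxslope) maxslope = slope;
    }
  }
  int m = from.size();
  IntegerMatrix edges(m, 2);
  for (int e = 0; e < m; ++e) {
    edges(e, 0) = from[e];
    edges(e, 1) = to[e];
  }
  return edges;
}
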
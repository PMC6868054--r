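#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Total overlap duration between two sorted, disjoint interval sets.
static double overlap2(const NumericVector& s1, const NumericVector& e1,
                       const NumericVector& s2, const NumericVector& e2) {
  int i = 0, j = 0;
  const int n1 = s1.size(), n2 = s2.size();
  double tot = 0.0;
  while (i < n1 && j < n2) {
    const double lo = std::max(s1[i], s2[j]);
    const double hi = std::min(e1[i], e2[j]);
    if (hi > lo) tot += hi - lo;
    if (e1[i] < e2[j])
      ++i;
    else
      ++j;
  }
  return tot;
}

// [[Rcpp::export]]
double cpp_interval_overlap(NumericVector s1, NumericVector e1,
                            NumericVector s2, NumericVector e2) {
  return overlap2(s1, e1, s2, e2);
}

// Time-weighted pairwise on-state overlaps for a set of neurons, given each
// neuron's merged on-intervals. `pairs` is a 2-column matrix of 0-based
// neuron indices; starts/ends are lists of sorted disjoint interval vectors.
// [[Rcpp::export]]
NumericVector cpp_pair_overlaps(List starts, List ends, IntegerMatrix pairs) {
  const int np = pairs.nrow();
  NumericVector out(np);
  for (int k = 0; k < np; ++k) {
    NumericVector s1 = starts[pairs(k, 0)], e1 = ends[pairs(k, 0)];
    NumericVector s2 = starts[pairs(k, 1)], e2 = ends[pairs(k, 1)];
    out[k] = overlap2(s1, e1, s2, e2);
  }
  return out;
}
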
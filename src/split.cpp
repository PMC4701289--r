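#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

inline double entropy_from_counts(const std::vector<int>& cnt, int total) {
  if (total <= 0) return 0.0;
  double h = 0.0, n = static_cast<double>(total);
  for (size_t c = 0; c < cnt.size(); ++c) {
    if (cnt[c] > 0) {
      double p = cnt[c] / n;
      h -= p * std::log2(p);
    }
  }
  return h;
}

} // namespace

// Exhaustive gain-ratio split search over all (attribute, midpoint)
// candidates of a node. y holds 1-based class codes in 1..nclass.
// Candidates require both branches to hold >= min_leaf instances.
// With gain_guard, the gain-ratio maximizer is taken only among
// candidates whose gain is at least the mean gain of all
// positive-gain candidates. Ties keep the lowest attribute index,
// then the lowest threshold (scan order).
// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, IntegerVector y, int nclass,
                    int min_leaf, bool gain_guard) {
  const int n = X.nrow(), p = X.ncol();
  if (n != y.size()) stop("X and y sizes differ");
  if (min_leaf < 1) min_leaf = 1;

  std::vector<int> parent(nclass, 0);
  for (int i = 0; i < n; ++i) {
    int cls = y[i];
    if (cls < 1 || cls > nclass) stop("class code out of range");
    parent[cls - 1]++;
  }
  const double h_parent = entropy_from_counts(parent, n);

  std::vector<int> attr_v;
  std::vector<double> thr_v, gain_v, si_v;
  attr_v.reserve(1024); thr_v.reserve(1024);
  gain_v.reserve(1024); si_v.reserve(1024);

  std::vector<int> ord(n);
  std::vector<int> left(nclass);
  const double eps = 1e-12;

  for (int j = 0; j < p; ++j) {
    NumericMatrix::Column col = X(_, j);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return col[a] < col[b]; });
    std::fill(left.begin(), left.end(), 0);
    for (int i = 0; i < n - 1; ++i) {
      left[y[ord[i]] - 1]++;
      double lo = col[ord[i]], hi = col[ord[i + 1]];
      if (!(lo < hi)) continue;               // not a distinct-value boundary
      int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      std::vector<int> right(nclass);
      for (int c = 0; c < nclass; ++c) right[c] = parent[c] - left[c];
      double hl = entropy_from_counts(left, nl);
      double hr = entropy_from_counts(right, nr);
      double pl = nl / static_cast<double>(n);
      double pr = nr / static_cast<double>(n);
      double gain = h_parent - pl * hl - pr * hr;
      if (gain <= eps) continue;
      double si = -pl * std::log2(pl) - pr * std::log2(pr);
      attr_v.push_back(j + 1);
      thr_v.push_back((lo + hi) / 2.0);
      gain_v.push_back(gain);
      si_v.push_back(si);
    }
  }

  if (attr_v.empty())
    return List::create(Named("found") = false);

  double mean_gain = 0.0;
  for (double g : gain_v) mean_gain += g;
  mean_gain /= static_cast<double>(gain_v.size());
  const double floor_gain = gain_guard ? mean_gain - eps : 0.0;

  int best = -1;
  double best_gr = -1.0;
  for (size_t i = 0; i < gain_v.size(); ++i) {
    if (gain_v[i] < floor_gain) continue;
    double gr = gain_v[i] / si_v[i];
    if (gr > best_gr + eps) { best_gr = gr; best = static_cast<int>(i); }
  }
  if (best < 0)
    return List::create(Named("found") = false);

  return List::create(
    Named("found") = true,
    Named("attribute_index") = attr_v[best],
    Named("threshold") = thr_v[best],
    Named("gain") = gain_v[best],
    Named("split_info") = si_v[best],
    Named("gain_ratio") = gain_v[best] / si_v[best]);
}
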
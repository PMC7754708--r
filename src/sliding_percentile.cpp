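#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// Sliding window percentile per row (neuron), window centered on each frame
// and truncated at the recording edges. Quantile definition matches R's
// type 7 (linear interpolation between order statistics) so the result is
// interchangeable with a brute-force per-frame quantile() recomputation.
// Window maintained as an ordered multiset; the low percentile used for
// baseline fluorescence sits near the bottom so the in-order walk to the
// k-th element is cheap.
// [[Rcpp::export]]
NumericMatrix sliding_percentile(NumericMatrix x, int halfwin, double prob) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    std::multiset<double> win;
    // initial window for t = 0: frames [0, halfwin]
    int hi = std::min(halfwin, nc - 1);
    for (int j = 0; j <= hi; ++j) win.insert(x(i, j));
    for (int t = 0; t < nc; ++t) {
      if (t > 0) {
        int add = t + halfwin;
        if (add <= nc - 1) win.insert(x(i, add));
        int drop = t - halfwin - 1;
        if (drop >= 0) win.erase(win.find(x(i, drop)));
      }
      const int n = (int)win.size();
      const double h = (n - 1) * prob;
      int k = (int)std::floor(h);
      if (k > n - 1) k = n - 1;
      const double g = h - k;
      std::multiset<double>::const_iterator it = win.begin();
      std::advance(it, k);
      double q = *it;
      if (g > 0.0 && k + 1 <= n - 1) {
        std::multiset<double>::const_iterator it2 = it;
        ++it2;
        q += g * (*it2 - q);
      }
      out(i, t) = q;
    }
  }
  return out;
}
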
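#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cross-chain atom pairs within a distance cutoff, found by a sweep over the
// x-axis: chain-B atoms are sorted by x and, for each chain-A atom, only the
// window |xB - xA| <= cutoff is examined. O(nA log nB + output) in practice,
// exact (no grid approximation); tests compare it against a naive all-pairs
// oracle in R.
// [[Rcpp::export(name = ".cross_pairs_within_cpp")]]
IntegerMatrix cross_pairs_within_cpp(NumericMatrix a, NumericMatrix b,
                                     double cutoff) {
  if (cutoff <= 0) stop("cutoff must be positive");
  int na = a.nrow(), nb = b.nrow();
  std::vector<int> order(nb);
  for (int j = 0; j < nb; ++j) order[j] = j;
  std::sort(order.begin(), order.end(),
            [&](int i, int j) { return b(i, 0) < b(j, 0); });
  std::vector<double> bx(nb);
  for (int j = 0; j < nb; ++j) bx[j] = b(order[j], 0);

  double cut2 = cutoff * cutoff;
  std::vector<int> ia, ib;
  for (int i = 0; i < na; ++i) {
    double xa = a(i, 0), ya = a(i, 1), za = a(i, 2);
    int lo = std::lower_bound(bx.begin(), bx.end(), xa - cutoff) - bx.begin();
    for (int k = lo; k < nb && bx[k] <= xa + cutoff; ++k) {
      int j = order[k];
      double dy = b(j, 1) - ya;
      if (std::fabs(dy) > cutoff) continue;
      double dz = b(j, 2) - za;
      if (std::fabs(dz) > cutoff) continue;
      double dx = b(j, 0) - xa;
      if (dx * dx + dy * dy + dz * dz <= cut2) {
        ia.push_back(i + 1);
        ib.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(ia.size(), 2);
  for (size_t k = 0; k < ia.size(); ++k) {
    out(k, 0) = ia[k];
    out(k, 1) = ib[k];
  }
  return out;
}
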
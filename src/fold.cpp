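#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Span-limited nested-structure folding with a simple base-pair energy
// model (GC/CG -3, AU/UA -2, GU/UG -1 kcal/mol, hairpin loop >= 3 nt).
// A "local structure" is a nested structure closed by a single outer base
// pair whose span does not exceed the window; the reported quantity is the
// energy of the most stable such structure. This deliberately does not
// reproduce nearest-neighbor (Turner) thermodynamics; it is a documented,
// deterministic stand-in with the same interface and invariants.

static const double INF = std::numeric_limits<double>::infinity();

static inline double pair_energy(int a, int b) {
  // bases: A=0, C=1, G=2, U=3; anything else (e.g. N) = -1
  if (a < 0 || b < 0) return INF;
  int lo = a < b ? a : b, hi = a < b ? b : a;
  if (lo == 1 && hi == 2) return -3.0;  // C-G
  if (lo == 0 && hi == 3) return -2.0;  // A-U
  if (lo == 2 && hi == 3) return -1.0;  // G-U
  return INF;
}

// [[Rcpp::export(name = ".fold_lowest_mfe")]]
double fold_lowest_mfe(IntegerVector codes, int window) {
  int n = codes.size();
  if (n < 5 || window < 5) return 0.0;
  int L = window < n ? window : n;  // max span of a closing pair
  // V[i][d]: best energy of a structure closed by pair (i, i+d);
  // M[i][d]: best energy (<= 0) of any nested structure within [i, i+d].
  std::vector<std::vector<double> > V(n, std::vector<double>(L, INF));
  std::vector<std::vector<double> > M(n, std::vector<double>(L, 0.0));
  double best = 0.0;
  for (int i = n - 1; i >= 0; --i) {
    for (int d = 4; d < L && i + d < n; ++d) {
      int j = i + d;
      // V: i pairs j, interior is the best structure in (i+1, j-1)
      double e = pair_energy(codes[i], codes[j]);
      if (e < INF) {
        double interior = (d - 2 >= 1) ? M[i + 1][d - 2] : 0.0;
        double v = e + interior;
        V[i][d] = v;
        if (v < best) best = v;
      }
      // M: j unpaired, or j pairs some k in [i, j-4]
      double m = M[i][d - 1];
      for (int k = i; k <= j - 4; ++k) {
        double vk = V[k][j - k];  // j - k <= d < L
        if (vk < INF) {
          double cand = (k > i ? M[i][k - 1 - i] : 0.0) + vk;
          if (cand < m) m = cand;
        }
      }
      M[i][d] = m < 0.0 ? m : 0.0;
    }
  }
  return best;
}
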
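// Single stem-loop minimum-free-energy folding.
//
// Dynamic program over closing pairs (i, j): a structure is a chain of
// nested base pairs with stacking energies between adjacent pairs, loop
// penalties for bulges/internal loops (total unpaired <= max_bulge), and a
// single terminal loop of at least min_loop unpaired bases. Multiloops are
// excluded by construction, which is what makes the model a pure hairpin
// caller rather than a general secondary-structure folder.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

static inline int enc(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': case 'U': return 3;
    default:  return -1;  // N or unknown: never pairs
  }
}

// pair strength (kcal/mol, positive): GC, AU, GU classes; 0 = not pairable
static inline double pair_strength(int a, int b, double sGC, double sAU,
                                   double sGU) {
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return sGC;  // C-G
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return sAU;  // A-U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return sGU;  // G-U
  return 0.0;
}

// [[Rcpp::export]]
List fold_hairpin_cpp(std::string seq, double sGC, double sAU, double sGU,
                      double loopA, double loopB, int min_loop,
                      int max_bulge) {
  const int n = (int) seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);

  std::string dots(n, '.');
  if (n < min_loop + 2) {
    return List::create(_["mfe"] = 0.0, _["structure"] = dots);
  }

  auto strength = [&](int i, int j) {
    if (s[i] < 0 || s[j] < 0) return 0.0;
    return pair_strength(s[i], s[j], sGC, sAU, sGU);
  };
  auto loop_pen = [&](int L) {
    double p = loopA + loopB * std::log((double) L / 4.0);
    return p > 0.0 ? p : 0.0;
  };

  // W[i][j]: min energy of a stem-loop closed by pair (i, j); column-major
  // over flattened index i * n + j. tb stores the inner pair for traceback
  // (-1 = terminal loop).
  std::vector<double> W((size_t) n * n, INF);
  std::vector<int> tbp((size_t) n * n, -1), tbq((size_t) n * n, -1);

  for (int d = min_loop + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      if (strength(i, j) <= 0.0) continue;
      double best = INF;
      int bp = -1, bq = -1;
      if (j - i - 1 >= min_loop) best = loop_pen(j - i - 1);
      int pmax = std::min(i + 1 + max_bulge, j - 1);
      for (int p = i + 1; p <= pmax; ++p) {
        int left = p - i - 1;
        int qmin = std::max(p + 1, j - 1 - (max_bulge - left));
        for (int q = j - 1; q >= qmin; --q) {
          double win = W[(size_t) p * n + q];
          if (!std::isfinite(win)) continue;
          double cost;
          if (p == i + 1 && q == j - 1) {
            cost = win - 0.5 * (strength(i, j) + strength(p, q));
          } else {
            cost = win + loop_pen(left + (j - q - 1));
          }
          if (cost < best) { best = cost; bp = p; bq = q; }
        }
      }
      W[(size_t) i * n + j] = best;
      tbp[(size_t) i * n + j] = bp;
      tbq[(size_t) i * n + j] = bq;
    }
  }

  // best closing pair overall; ties -> smallest (i, j)
  double mfe = 0.0;
  int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = i + min_loop + 1; j < n; ++j) {
      double w = W[(size_t) i * n + j];
      if (w < mfe - 1e-12) { mfe = w; bi = i; bj = j; }
    }
  }
  if (bi < 0) {
    return List::create(_["mfe"] = 0.0, _["structure"] = dots);
  }

  int i = bi, j = bj;
  while (i >= 0) {
    dots[i] = '(';
    dots[j] = ')';
    int p = tbp[(size_t) i * n + j];
    int q = tbq[(size_t) i * n + j];
    i = p; j = q;
  }
  return List::create(_["mfe"] = mfe, _["structure"] = dots);
}
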
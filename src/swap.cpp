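// Fixed-margin randomization of a binary matrix by 2x2 checkerboard
// swaps.  A swap replaces a submatrix [[1,0],[0,1]] by [[0,1],[1,0]] (or
// vice versa), which preserves every row and column sum exactly.  Uses
// R's RNG so set.seed() on the R side controls the stream.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cpp_checkerboard_swap(IntegerMatrix m, int target_swaps,
                                    double max_trials) {
  IntegerMatrix out = clone(m);
  int nr = out.nrow(), nc = out.ncol();
  if (nr < 2 || nc < 2 || target_swaps <= 0) return out;
  int swaps = 0;
  double trials = 0.0;
  while (swaps < target_swaps && trials < max_trials) {
    trials += 1.0;
    int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * nr);
    if (r1 == r2) continue;
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * nc);
    if (c1 == c2) continue;
    int a = out(r1, c1), b = out(r1, c2), c = out(r2, c1), d = out(r2, c2);
    if (a == 1 && d == 1 && b == 0 && c == 0) {
      out(r1, c1) = 0; out(r2, c2) = 0; out(r1, c2) = 1; out(r2, c1) = 1;
      ++swaps;
    } else if (a == 0 && d == 0 && b == 1 && c == 1) {
      out(r1, c1) = 1; out(r2, c2) = 1; out(r1, c2) = 0; out(r2, c1) = 0;
      ++swaps;
    }
  }
  return out;
}
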
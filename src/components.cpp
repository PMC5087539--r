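#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a logical mask.  conn = 8 (default for
// segmentation objects) or 4 (used for hole detection).  Labels are
// 1..n_components in scan order; background is 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int conn = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int adr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int adc8[8] = {-1,  0,  1, -1, 1, -1, 0, 1};
  const int adr4[4] = {-1, 0, 0, 1};
  const int adc4[4] = { 0, -1, 1, 0};
  const int *adr = conn == 8 ? adr8 : adr4;
  const int *adc = conn == 8 ? adc8 : adc4;
  int nn = conn == 8 ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + nr * c);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = rr + adr[k], c2 = cc + adc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + nr * c2);
          }
        }
      }
    }
  }
  return lab;
}
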
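#include <Rcpp.h>
using namespace Rcpp;

// Windowed GLCM contrast fused over displacement vectors by a min operator.
// For each pixel the co-occurrence contrast of the centred (truncated at the
// image border) window is computed for every displacement; the per-pixel
// result is the minimum over displacements.  With a symmetrised, normalised
// GLCM the contrast reduces to the mean squared gray-level difference over
// the directed co-occurring pixel pairs, so no explicit matrix is built.
// [[Rcpp::export]]
NumericMatrix cpp_pantex(IntegerMatrix q, int window, IntegerVector drow,
                         IntegerVector dcol) {
  int nr = q.nrow(), nc = q.ncol(), m = drow.size();
  int h = (window - 1) / 2;
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int r0 = r - h < 0 ? 0 : r - h;
      int r1 = r + h >= nr ? nr - 1 : r + h;
      int c0 = c - h < 0 ? 0 : c - h;
      int c1 = c + h >= nc ? nc - 1 : c + h;
      double best = R_PosInf;
      for (int k = 0; k < m; ++k) {
        int dr = drow[k], dc = dcol[k];
        long n = 0; double s = 0.0;
        int rr0 = r0, rr1 = r1, cc0 = c0, cc1 = c1;
        if (dr > 0) rr1 -= dr; else rr0 -= dr;
        if (dc > 0) cc1 -= dc; else cc0 -= dc;
        for (int cc = cc0; cc <= cc1; ++cc) {
          for (int rr = rr0; rr <= rr1; ++rr) {
            double d = q(rr, cc) - q(rr + dr, cc + dc);
            s += d * d;
            ++n;
          }
        }
        if (n > 0) {
          double contrast = s / n;
          if (contrast < best) best = contrast;
        }
      }
      out(r, c) = (best == R_PosInf) ? 0.0 : best;
    }
  }
  return out;
}

// 3x3 local variance (population variance over the truncated
// neighbourhood); two-pass so flat neighbourhoods give exactly zero.
// [[Rcpp::export]]
NumericMatrix cpp_local_variance3(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double s = 0; int n = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          s += x(rr, cc); ++n;
        }
      }
      double mu = s / n, acc = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          double d = x(rr, cc) - mu;
          acc += d * d;
        }
      }
      out(r, c) = acc / n;
    }
  }
  return out;
}
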
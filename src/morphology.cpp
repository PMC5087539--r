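#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Grayscale morphological reconstruction by dilation, 8-connectivity.
// Hybrid algorithm: forward/backward raster sweeps, then FIFO propagation.
// marker must be <= mask pointwise; the result is the largest image J with
// J <= mask whose peaks are connected to peaks of the marker.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix J = clone(marker);

  // neighbour offsets split into the raster-order "before" (N+) and
  // "after" (N-) halves used by the sweeps
  // sweeps run column-major (r inner), so the "earlier" half-neighbourhood
  // is the previous column plus the pixel above
  const int ndr[4] = {-1,  0,  1, -1};
  const int ndc[4] = {-1, -1, -1,  0};

  // forward sweep
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + ndr[k], cc = c + ndc[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && J(rr, cc) > v)
          v = J(rr, cc);
      }
      if (v > mask(r, c)) v = mask(r, c);
      J(r, c) = v;
    }
  }
  // backward sweep + queue seeding
  std::queue<std::pair<int,int> > fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r - ndr[k], cc = c - ndc[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && J(rr, cc) > v)
          v = J(rr, cc);
      }
      if (v > mask(r, c)) v = mask(r, c);
      J(r, c) = v;
      for (int k = 0; k < 4; ++k) {
        int rr = r - ndr[k], cc = c - ndc[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
            J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) {
          fifo.push(std::make_pair(r, c));
          break;
        }
      }
    }
  }
  const int adr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int adc[8] = {-1,  0,  1, -1, 1, -1, 0, 1};
  while (!fifo.empty()) {
    std::pair<int,int> p = fifo.front(); fifo.pop();
    int r = p.first, c = p.second;
    for (int k = 0; k < 8; ++k) {
      int rr = r + adr[k], cc = c + adc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < J(r, c) && mask(rr, cc) != J(rr, cc)) {
        double v = J(r, c) < mask(rr, cc) ? J(r, c) : mask(rr, cc);
        if (v > J(rr, cc)) {
          J(rr, cc) = v;
          fifo.push(std::make_pair(rr, cc));
        }
      }
    }
  }
  return J;
}

// Flat erosion by an arbitrary offset set; out-of-bounds offsets are ignored
// (border handling equivalent to padding with +Inf).
// [[Rcpp::export]]
NumericMatrix cpp_erode_offsets(NumericMatrix img, IntegerVector drow,
                                IntegerVector dcol) {
  int nr = img.nrow(), nc = img.ncol(), m = drow.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = R_PosInf;
      for (int k = 0; k < m; ++k) {
        int rr = r + drow[k], cc = c + dcol[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && img(rr, cc) < v)
          v = img(rr, cc);
      }
      out(r, c) = v;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_dilate_offsets(NumericMatrix img, IntegerVector drow,
                                 IntegerVector dcol) {
  int nr = img.nrow(), nc = img.ncol(), m = drow.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = R_NegInf;
      for (int k = 0; k < m; ++k) {
        int rr = r + drow[k], cc = c + dcol[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && img(rr, cc) > v)
          v = img(rr, cc);
      }
      out(r, c) = v;
    }
  }
  return out;
}
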
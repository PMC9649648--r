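// Exact area-average resize: every output pixel integrates the input over
// its (fractional) source box.  Used to bring 299 px tiles to the CNN
// input size without discarding border content, identically at training
// and inference.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_resize_area(NumericVector img, int h2, int w2) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  NumericVector out(h2 * w2 * C);
  out.attr("dim") = IntegerVector::create(h2, w2, C);
  const double sy = (double)H / h2, sx = (double)W / w2;
  for (int c = 0; c < C; ++c) {
    const double* in = img.begin() + (size_t)c * H * W;
    double* o = out.begin() + (size_t)c * h2 * w2;
    for (int j = 0; j < w2; ++j) {
      double xa = j * sx, xb = (j + 1) * sx;
      int jx0 = (int)xa, jx1 = std::min(W - 1, (int)std::ceil(xb) - 1);
      for (int i = 0; i < h2; ++i) {
        double ya = i * sy, yb = (i + 1) * sy;
        int iy0 = (int)ya, iy1 = std::min(H - 1, (int)std::ceil(yb) - 1);
        double acc = 0, wsum = 0;
        for (int jj = jx0; jj <= jx1; ++jj) {
          double wx = std::min(xb, (double)jj + 1) - std::max(xa, (double)jj);
          for (int ii = iy0; ii <= iy1; ++ii) {
            double wy = std::min(yb, (double)ii + 1) - std::max(ya, (double)ii);
            acc += wx * wy * in[ii + (size_t)jj * H];
            wsum += wx * wy;
          }
        }
        o[i + (size_t)j * h2] = acc / wsum;
      }
    }
  }
  return out;
}
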
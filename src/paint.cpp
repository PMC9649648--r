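// In-place canvas painting for the synthetic-histology renderer.  Canvas
// arrays live privately inside the generator's canvas environment and are
// never aliased, so reference-semantics mutation is safe and avoids
// copying multi-megapixel arrays per painted primitive.

#include <Rcpp.h>
using namespace Rcpp;

// Alpha-blend a color into an H*W*3 canvas at 1-based pixel indices.
// [[Rcpp::export]]
void cpp_paint(NumericVector img, IntegerVector idx, NumericVector color,
               double alpha, double shade, int npx) {
  for (int k = 0; k < 3; ++k) {
    double col = std::min(color[k] * shade, 1.0);
    for (int i = 0; i < idx.size(); ++i) {
      int j = idx[i] - 1 + k * npx;
      img[j] = (1 - alpha) * img[j] + alpha * col;
    }
  }
}

// Set mask pixels, returning how many were newly set.
// [[Rcpp::export]]
int cpp_mask_set(LogicalVector mask, IntegerVector idx) {
  int fresh = 0;
  for (int i = 0; i < idx.size(); ++i) {
    int j = idx[i] - 1;
    if (!mask[j]) { mask[j] = TRUE; ++fresh; }
  }
  return fresh;
}
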
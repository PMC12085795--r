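#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Local Shannon entropy of every patch-size x patch-size window of an 8-bit
// image, top-left positions on a stride grid. A 256-bin histogram slides
// along each output row (add/remove `stride` columns per step), so the cost
// is O(rows * cols * patch * stride + cells * 256) instead of
// O(cells * patch^2).
//
// Entropy is computed as -sum_i (c_i/t) log2(c_i/t) over occupied bins in
// ascending bin order, matching the R-level reference computation.

static inline double hist_entropy(const int *hist, double total) {
  double h = 0.0;
  for (int i = 0; i < 256; ++i) {
    if (hist[i] > 0) {
      double p = hist[i] / total;
      h -= p * std::log2(p);
    }
  }
  return h;
}

// [[Rcpp::export]]
NumericMatrix entropy_map_cpp(IntegerMatrix img, int patch, int stride) {
  const int H = img.nrow(), W = img.ncol();
  if (patch < 1 || patch > H || patch > W)
    stop("patch size must be between 1 and the image dimensions");
  if (stride < 1) stop("stride must be >= 1");

  const int nr = (H - patch) / stride + 1;
  const int nc = (W - patch) / stride + 1;
  NumericMatrix out(nr, nc);
  const double total = (double)patch * (double)patch;
  std::vector<int> hist(256);

  for (int orow = 0; orow < nr; ++orow) {
    const int r0 = orow * stride;
    std::fill(hist.begin(), hist.end(), 0);
    // initial window at column 0
    for (int c = 0; c < patch; ++c)
      for (int r = 0; r < patch; ++r) {
        int v = img(r0 + r, c);
        if (v < 0 || v > 255) stop("image values must lie in [0, 255]");
        ++hist[v];
      }
    out(orow, 0) = hist_entropy(hist.data(), total);
    for (int ocol = 1; ocol < nc; ++ocol) {
      const int cprev = (ocol - 1) * stride, cnew = ocol * stride;
      // columns leaving / entering the window (windows may be disjoint
      // when stride >= patch)
      for (int c = cprev; c < std::min(cnew, cprev + patch); ++c)
        for (int r = 0; r < patch; ++r) --hist[img(r0 + r, c)];
      for (int c = std::max(cnew, cprev + patch); c < cnew + patch; ++c)
        for (int r = 0; r < patch; ++r) {
          int v = img(r0 + r, c);
          if (v < 0 || v > 255) stop("image values must lie in [0, 255]");
          ++hist[v];
        }
      out(orow, ocol) = hist_entropy(hist.data(), total);
    }
  }
  return out;
}
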
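#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Exhaustive block matching inside a square search window.
//
// guide: H x W x Q array (column-major), the prefiltered image the distances
// are computed on. ref_i/ref_j: 1-based top-left corner of the reference
// block. Candidates are all top-left corners within +/- radius of the
// reference corner whose m x m x Q block lies fully inside the image.
// Distance is ||a - b||_2^2 / (m * m * Q). Blocks with distance <= tau_d are
// kept, sorted ascending by distance with raster-order (row-major corner
// index) tie-breaking; the reference block is always first; the list is
// truncated to l_max entries.
//
// Returns an integer matrix of 1-based (i, j) corners, one row per block.
// [[Rcpp::export(name = ".match_blocks_cpp")]]
Rcpp::IntegerMatrix match_blocks_cpp(Rcpp::NumericVector guide,
                                     int H, int W, int Q,
                                     int ref_i, int ref_j,
                                     int m, int radius,
                                     double tau_d, int l_max) {
  const double *g = guide.begin();
  const int ri = ref_i - 1, rj = ref_j - 1;
  if (ri < 0 || rj < 0 || ri + m > H || rj + m > W)
    Rcpp::stop("reference block out of bounds");

  const int i_lo = std::max(0, ri - radius);
  const int i_hi = std::min(H - m, ri + radius);
  const int j_lo = std::max(0, rj - radius);
  const int j_hi = std::min(W - m, rj + radius);
  const double npix = (double)m * m * Q;

  struct Cand { double d; int key; int i; int j; };
  std::vector<Cand> kept;
  kept.reserve((i_hi - i_lo + 1) * (j_hi - j_lo + 1));

  for (int i = i_lo; i <= i_hi; ++i) {
    for (int j = j_lo; j <= j_hi; ++j) {
      double ss = 0.0;
      for (int q = 0; q < Q; ++q) {
        const double *ref_q = g + (size_t)q * H * W;
        for (int c = 0; c < m; ++c) {
          const double *a = ref_q + (size_t)(rj + c) * H + ri;
          const double *b = ref_q + (size_t)(j + c) * H + i;
          for (int r = 0; r < m; ++r) {
            const double diff = a[r] - b[r];
            ss += diff * diff;
          }
        }
      }
      const double d = ss / npix;
      if (i == ri && j == rj) {
        kept.push_back({-1.0, i * W + j, i, j});  // force reference first
      } else if (d <= tau_d) {
        kept.push_back({d, i * W + j, i, j});
      }
    }
  }

  std::stable_sort(kept.begin(), kept.end(),
                   [](const Cand &a, const Cand &b) {
                     if (a.d != b.d) return a.d < b.d;
                     return a.key < b.key;
                   });
  const int L = std::min((int)kept.size(), l_max);
  Rcpp::IntegerMatrix out(L, 2);
  for (int k = 0; k < L; ++k) {
    out(k, 0) = kept[k].i + 1;
    out(k, 1) = kept[k].j + 1;
  }
  return out;
}
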
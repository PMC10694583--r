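#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Masked order-statistic / weighted-average filters for phasor rasters.
// Windows are clipped at image borders and only pixels flagged valid in
// `mask` contribute; a centre pixel with no valid neighbours keeps its
// input value.

// [[Rcpp::export(name = ".masked_median_filter")]]
NumericMatrix masked_median_filter(NumericMatrix x, LogicalMatrix mask,
                                   int window) {
  if (window < 3 || window % 2 == 0)
    stop("`window` must be an odd integer >= 3");
  int nr = x.nrow(), nc = x.ncol(), r = window / 2;
  NumericMatrix out = clone(x);
  std::vector<double> buf;
  buf.reserve((size_t)window * window);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      buf.clear();
      for (int dj = std::max(0, j - r); dj <= std::min(nc - 1, j + r); ++dj)
        for (int di = std::max(0, i - r); di <= std::min(nr - 1, i + r); ++di)
          if (mask(di, dj) && R_finite(x(di, dj))) buf.push_back(x(di, dj));
      size_t n = buf.size();
      if (n == 0) continue;
      size_t mid = n / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        med = 0.5 * (med + lo);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".masked_gaussian_filter")]]
NumericMatrix masked_gaussian_filter(NumericMatrix x, LogicalMatrix mask,
                                     double sigma) {
  if (sigma <= 0) stop("`sigma` must be > 0");
  int nr = x.nrow(), nc = x.ncol();
  int r = (int)std::ceil(3.0 * sigma);
  NumericMatrix out = clone(x);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      double acc = 0.0, wsum = 0.0;
      for (int dj = std::max(0, j - r); dj <= std::min(nc - 1, j + r); ++dj) {
        for (int di = std::max(0, i - r); di <= std::min(nr - 1, i + r); ++di) {
          if (!mask(di, dj) || !R_finite(x(di, dj))) continue;
          double d2 = (double)(di - i) * (di - i) + (double)(dj - j) * (dj - j);
          double w = std::exp(-d2 / (2.0 * sigma * sigma));
          acc += w * x(di, dj);
          wsum += w;
        }
      }
      if (wsum > 0) out(i, j) = acc / wsum;
    }
  }
  return out;
}
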
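#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sliding-window median with edge replication. Keeps the output on the
// input's native intensity scale (no quantization), so every output value
// is a member of the input's value set.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(const NumericMatrix& img, const int k) {
  const int h = img.nrow(), w = img.ncol();
  const int r = k / 2, n = k * k;
  NumericMatrix out(h, w);
  std::vector<double> buf(n);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int m = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = std::min(std::max(j + dj, 0), w - 1);
        for (int di = -r; di <= r; ++di) {
          int ii = std::min(std::max(i + di, 0), h - 1);
          buf[m++] = img(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      out(i, j) = buf[n / 2];
    }
  }
  return out;
}
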
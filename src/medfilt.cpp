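#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 2-D median filter with replicated borders. k must be odd.
// [[Rcpp::export]]
NumericMatrix median_filter_2d(NumericMatrix x, int k) {
  if (k < 1 || k % 2 == 0) stop("kernel size must be an odd positive integer");
  int nr = x.nrow(), nc = x.ncol(), r = (k - 1) / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)k * k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -r; dj <= r; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -r; di <= r; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          buf.push_back(x(ii, jj));
        }
      }
      size_t m = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      out(i, j) = buf[m];
    }
  }
  return out;
}
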
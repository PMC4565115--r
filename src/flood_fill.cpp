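#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 4-connected flood fill: selects pixels reachable from the seed through
// pixels whose intensity lies within +/- tol of the seed intensity.
// seed_row / seed_col are 1-based (R convention).
// [[Rcpp::export]]
LogicalMatrix flood_fill_cpp(NumericMatrix img, int seed_row, int seed_col,
                             double tol) {
  const int nr = img.nrow(), nc = img.ncol();
  const int sr = seed_row - 1, sc = seed_col - 1;
  if (sr < 0 || sr >= nr || sc < 0 || sc >= nc)
    stop("seed out of bounds");
  const double sv = img(sr, sc);
  LogicalMatrix out(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  out(sr, sc) = true;
  stack.push_back(sr + nr * sc);
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    const int p = stack.back();
    stack.pop_back();
    const int r = p % nr, c = p / nr;
    for (int k = 0; k < 4; ++k) {
      const int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!out(r2, c2) && std::fabs(img(r2, c2) - sv) <= tol) {
        out(r2, c2) = true;
        stack.push_back(r2 + nr * c2);
      }
    }
  }
  return out;
}

// 3x3 median filter with edge replication.
// [[Rcpp::export]]
NumericMatrix median3x3_cpp(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double v[9];
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int k = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        int c2 = std::min(std::max(c + dc, 0), nc - 1);
        for (int dr = -1; dr <= 1; ++dr) {
          int r2 = std::min(std::max(r + dr, 0), nr - 1);
          v[k++] = img(r2, c2);
        }
      }
      std::nth_element(v, v + 4, v + 9);
      out(r, c) = v[4];
    }
  }
  return out;
}
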
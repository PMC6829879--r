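#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median filter with a k x k square window and replicated (clamped) borders.
// Exact order-statistic median per window; k must be odd.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int k) {
  int h = img.nrow(), w = img.ncol(), r = k / 2;
  NumericMatrix out(h, w);
  std::vector<double> win(k * k);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int n = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = std::min(std::max(j + dj, 0), w - 1);
        for (int di = -r; di <= r; ++di) {
          int ii = std::min(std::max(i + di, 0), h - 1);
          win[n++] = img(ii, jj);
        }
      }
      std::nth_element(win.begin(), win.begin() + n / 2, win.begin() + n);
      out(i, j) = win[n / 2];
    }
  }
  return out;
}

// Hysteresis linking: keep weak pixels 8-connected to a strong pixel.
// BFS seeded at strong pixels, constrained to the weak mask.
// [[Rcpp::export]]
LogicalMatrix hysteresis_cpp(LogicalMatrix weak, LogicalMatrix strong) {
  int h = weak.nrow(), w = weak.ncol();
  LogicalMatrix out(h, w);
  std::vector<int> stack;
  stack.reserve(256);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      if (strong(i, j) && weak(i, j)) {
        out(i, j) = true;
        stack.push_back(j * h + i);
      }
  while (!stack.empty()) {
    int p = stack.back();
    stack.pop_back();
    int i = p % h, j = p / h;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int ii = i + di, jj = j + dj;
        if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
        if (weak(ii, jj) && !out(ii, jj)) {
          out(ii, jj) = true;
          stack.push_back(jj * h + ii);
        }
      }
  }
  return out;
}

// Hough voting: for each edge pixel (x, y), one vote per theta bin at the
// rho bin nearest x*cos(theta) + y*sin(theta). Rho bin centers are
// -d + (j-1)*rho_step, j = 1..n_rho. Returns n_theta x n_rho count matrix.
// [[Rcpp::export]]
IntegerMatrix hough_accumulate_cpp(NumericVector x, NumericVector y,
                                   NumericVector theta, double d,
                                   double rho_step, int n_rho) {
  int m = x.size(), n_theta = theta.size();
  IntegerMatrix acc(n_theta, n_rho);
  for (int t = 0; t < n_theta; ++t) {
    double ct = std::cos(theta[t]), st = std::sin(theta[t]);
    for (int p = 0; p < m; ++p) {
      double rho = x[p] * ct + y[p] * st;
      int j = (int) std::lround((rho + d) / rho_step);
      if (j < 0) j = 0;
      if (j >= n_rho) j = n_rho - 1;
      acc(t, j) += 1;
    }
  }
  return acc;
}
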
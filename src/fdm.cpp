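#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Sliding-window differential box counting.
//
// Input is the image already padded by (window - 1) / 2 on every side; the
// returned map covers the unpadded interior. For each scale s (2 ..
// window/2) the window is partitioned into floor(window/s)^2 cells of
// s x s pixels (remainder rows/cols ignored) and each cell contributes
// floor(max/h) - floor(min/h) + 1 boxes, with box height h = s * G / window
// on a G-level grey scaling of the whole plane. The fractal dimension is
// the least-squares slope of log N(s) against log(window/s).
//
// Cell extrema are shared between overlapping windows: for each scale the
// s x s sliding min/max over the padded plane is computed once (separable
// two-pass), then every window sums the counts of its own cell anchors.

static void sliding_extrema_1d(const std::vector<double>& in, int n, int m,
                               int s, std::vector<double>& mn,
                               std::vector<double>& mx) {
  // row-major n x m input; extrema over horizontal runs of length s,
  // anchored at the left; output width m - s + 1
  int mo = m - s + 1;
  for (int i = 0; i < n; ++i) {
    const double* row = &in[(size_t)i * m];
    for (int j = 0; j < mo; ++j) {
      double lo = row[j], hi = row[j];
      for (int k = 1; k < s; ++k) {
        double v = row[j + k];
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      mn[(size_t)i * mo + j] = lo;
      mx[(size_t)i * mo + j] = hi;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix dbc_fdm_cpp(NumericMatrix padded, int window) {
  const int half = (window - 1) / 2;
  const int np = padded.nrow(), mp = padded.ncol();
  const int n = np - 2 * half, m = mp - 2 * half;
  if (n < 1 || m < 1) stop("padded image smaller than the window");
  if (window < 7 || window % 2 == 0) stop("window must be odd and >= 7");

  const double G = 255.0;
  double lo = padded(0, 0), hi = padded(0, 0);
  for (int j = 0; j < mp; ++j)
    for (int i = 0; i < np; ++i) {
      double v = padded(i, j);
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
  const double range = hi - lo;

  // row-major copy of the grey-scaled plane
  std::vector<double> img((size_t)np * mp);
  for (int i = 0; i < np; ++i)
    for (int j = 0; j < mp; ++j)
      img[(size_t)i * mp + j] =
          range > 0 ? (padded(i, j) - lo) / range * G : 0.0;

  std::vector<int> scales;
  for (int s = 2; s <= window / 2; ++s) scales.push_back(s);
  const int ns = (int)scales.size();
  if (ns < 2) stop("window too small for box counting (needs >= 2 scales)");

  std::vector<double> xs(ns), logN((size_t)ns * n * m);
  for (int si = 0; si < ns; ++si) {
    int s = scales[si];
    xs[si] = std::log((double)window / s);
    int cells = window / s;  // per side, remainder ignored

    // two-pass sliding s x s extrema, anchored top-left
    int mo = mp - s + 1, no = np - s + 1;
    std::vector<double> hmn((size_t)np * mo), hmx((size_t)np * mo);
    sliding_extrema_1d(img, np, mp, s, hmn, hmx);
    std::vector<double> cmn((size_t)no * mo), cmx((size_t)no * mo);
    for (int j = 0; j < mo; ++j) {
      for (int i = 0; i < no; ++i) {
        double a = hmn[(size_t)i * mo + j], b = hmx[(size_t)i * mo + j];
        for (int k = 1; k < s; ++k) {
          double va = hmn[(size_t)(i + k) * mo + j];
          double vb = hmx[(size_t)(i + k) * mo + j];
          if (va < a) a = va;
          if (vb > b) b = vb;
        }
        cmn[(size_t)i * mo + j] = a;
        cmx[(size_t)i * mo + j] = b;
      }
    }

    const double h = (double)s * G / window;
    for (int pi = 0; pi < n; ++pi) {
      for (int pj = 0; pj < m; ++pj) {
        // window top-left corner in padded coordinates
        int wy = pi, wx = pj;  // pixel (pi+half, pj+half) - half
        double N = 0.0;
        for (int cy = 0; cy < cells; ++cy) {
          int ay = wy + cy * s;
          for (int cx = 0; cx < cells; ++cx) {
            int ax = wx + cx * s;
            double cmin = cmn[(size_t)ay * mo + ax];
            double cmax = cmx[(size_t)ay * mo + ax];
            N += std::floor(cmax / h) - std::floor(cmin / h) + 1.0;
          }
        }
        logN[(size_t)si * n * m + (size_t)pi * m + pj] = std::log(N);
      }
    }
  }

  // per-pixel least-squares slope of logN against xs
  double xbar = 0.0;
  for (int si = 0; si < ns; ++si) xbar += xs[si];
  xbar /= ns;
  double sxx = 0.0;
  for (int si = 0; si < ns; ++si) sxx += (xs[si] - xbar) * (xs[si] - xbar);

  NumericMatrix out(n, m);
  for (int pi = 0; pi < n; ++pi) {
    for (int pj = 0; pj < m; ++pj) {
      double sxy = 0.0, ybar = 0.0;
      for (int si = 0; si < ns; ++si)
        ybar += logN[(size_t)si * n * m + (size_t)pi * m + pj];
      ybar /= ns;
      for (int si = 0; si < ns; ++si)
        sxy += (xs[si] - xbar) *
               (logN[(size_t)si * n * m + (size_t)pi * m + pj] - ybar);
      out(pi, pj) = sxy / sxx;
    }
  }
  return out;
}
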
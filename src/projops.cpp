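#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of img at (x, y) in pixel coordinates measured from the
// image centre; returns 0 outside the grid (zero-padded object assumption).
static inline double sample_bilinear(const NumericMatrix& img, double x, double y) {
  const int nr = img.nrow(), nc = img.ncol();
  const double cx = 0.5 * (nc - 1), cy = 0.5 * (nr - 1);
  const double col = x + cx, row = y + cy;
  const int c0 = (int)std::floor(col), r0 = (int)std::floor(row);
  if (c0 < -1 || c0 > nc - 1 || r0 < -1 || r0 > nr - 1) return 0.0;
  const double fc = col - c0, fr = row - r0;
  double v00 = 0.0, v01 = 0.0, v10 = 0.0, v11 = 0.0;
  if (r0 >= 0 && c0 >= 0)           v00 = img(r0, c0);
  if (r0 >= 0 && c0 + 1 <= nc - 1)  v01 = img(r0, c0 + 1);
  if (r0 + 1 <= nr - 1 && c0 >= 0)  v10 = img(r0 + 1, c0);
  if (r0 + 1 <= nr - 1 && c0 + 1 <= nc - 1) v11 = img(r0 + 1, c0 + 1);
  return (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11);
}

// Parallel-beam forward projection (Radon transform).
// Rows of the result are angles, columns detector bins; bin spacing is one
// pixel and line integrals are Riemann sums with one-pixel steps, so values
// are in units of (pixel value) x (pixel side).  Detector bin b maps to
// signed offset s = b - (n_bins - 1) / 2 along (cos a, sin a) in (x, y).
// [[Rcpp::export]]
NumericMatrix cpp_radon(NumericMatrix img, NumericVector angles_rad, int n_bins) {
  const int na = angles_rad.size();
  const int nu = n_bins;  // integration steps along each ray
  NumericMatrix sino(na, n_bins);
  const double mid = 0.5 * (n_bins - 1);
  for (int a = 0; a < na; ++a) {
    const double ca = std::cos(angles_rad[a]), sa = std::sin(angles_rad[a]);
    for (int b = 0; b < n_bins; ++b) {
      const double s = b - mid;
      double acc = 0.0;
      for (int u = 0; u < nu; ++u) {
        const double t = u - mid;
        // x = s*cos - t*sin ; y = s*sin + t*cos
        acc += sample_bilinear(img, s * ca - t * sa, s * sa + t * ca);
      }
      sino(a, b) = acc;
    }
  }
  return sino;
}

// Backprojection of a (filtered) sinogram onto an n x n grid, with linear
// interpolation between detector bins.  The caller applies the pi/(2 * n_a)
// quadrature weight (angles assumed uniform over [0, pi)).
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix sino, NumericVector angles_rad, int n) {
  const int na = angles_rad.size(), nb = sino.ncol();
  const double mid = 0.5 * (nb - 1), c = 0.5 * (n - 1);
  NumericMatrix out(n, n);
  for (int a = 0; a < na; ++a) {
    const double ca = std::cos(angles_rad[a]), sa = std::sin(angles_rad[a]);
    for (int col = 0; col < n; ++col) {
      const double x = col - c;
      for (int row = 0; row < n; ++row) {
        const double y = row - c;
        const double s = x * ca + y * sa + mid;
        const int b0 = (int)std::floor(s);
        if (b0 < 0 || b0 >= nb - 1) continue;
        const double f = s - b0;
        out(row, col) += (1 - f) * sino(a, b0) + f * sino(a, b0 + 1);
      }
    }
  }
  return out;
}
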
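#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of m at fractional (row, col); zero outside the grid.
static inline double bilin(const NumericMatrix& m, double r, double c) {
  const int nr = m.nrow(), nc = m.ncol();
  if (r < 0.0 || c < 0.0 || r > nr - 1 || c > nc - 1) return 0.0;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  if (r0 == nr - 1) r0--;
  if (c0 == nc - 1) c0--;
  const double fr = r - r0, fc = c - c0;
  const double v00 = m(r0, c0),     v01 = m(r0, c0 + 1);
  const double v10 = m(r0 + 1, c0), v11 = m(r0 + 1, c0 + 1);
  return (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11);
}

// Discrete Radon transform of one square slice.
// Convention: slice center at ((n-1)/2, (n-1)/2); x = col - cx, y = row - cy;
// detector coordinate u = x*cos(theta) + y*sin(theta); at theta = 0 the ray
// integrates along rows. Returns n_angles x det_width, values are line
// integrals (sum * pixel_size).
// [[Rcpp::export]]
NumericMatrix cpp_forward_project(const NumericMatrix& slice,
                                  const NumericVector& angles,
                                  const int det_width,
                                  const double pixel_size) {
  const int n = slice.nrow();
  if (slice.ncol() != n) stop("slice must be square");
  const int na = angles.size();
  const double cx = (n - 1) / 2.0;
  const double u0 = (det_width - 1) / 2.0;
  const int smax = n / 2;
  NumericMatrix sino(na, det_width);
  for (int a = 0; a < na; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    for (int t = 0; t < det_width; ++t) {
      const double u = t - u0;
      double acc = 0.0;
      for (int s = -smax; s <= smax; ++s) {
        const double x = u * ca - s * sa;
        const double y = u * sa + s * ca;
        acc += bilin(slice, y + cx, x + cx);
      }
      sino(a, t) = acc * pixel_size;
    }
  }
  return sino;
}

// Backprojection of a ramp-filtered sinogram (det_width x n_angles) onto a
// grid x grid slice. Linear interpolation along the detector, output masked
// to the reconstruction circle, scaled by pi / (2 n_angles) / pixel_size so
// that attenuation comes back in the units the line integrals were taken in.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(const NumericMatrix& fsino,
                              const NumericVector& angles,
                              const int grid,
                              const double pixel_size) {
  const int W = fsino.nrow();
  const int na = angles.size();
  if (fsino.ncol() != na) stop("fsino must be det_width x n_angles");
  const double c = (grid - 1) / 2.0;
  const double u0 = (W - 1) / 2.0;
  const double rad = grid / 2.0;
  const double scale = M_PI / (2.0 * na) / pixel_size;
  NumericMatrix out(grid, grid);
  // angle-major accumulation: along a column of the output the detector
  // coordinate advances by sin(theta) per row, so the inner loop is a
  // strength-reduced linear interpolation sweep
  for (int a = 0; a < na; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    const double* fp = &fsino(0, a);
    for (int col = 0; col < grid; ++col) {
      const double x = col - c;
      const double h2 = rad * rad - x * x;
      if (h2 < 0.0) continue;
      const double h = std::sqrt(h2);
      int r0 = (int)std::ceil(c - h), r1 = (int)std::floor(c + h);
      if (r0 < 0) r0 = 0;
      if (r1 > grid - 1) r1 = grid - 1;
      double* op = &out(0, col);
      double u = x * ca + (r0 - c) * sa + u0;
      for (int row = r0; row <= r1; ++row, u += sa) {
        if (u >= 0.0 && u <= W - 1) {
          int i = (int)u;
          if (i == W - 1) i--;
          const double f = u - i;
          op[row] += fp[i] + f * (fp[i + 1] - fp[i]);
        }
      }
    }
  }
  const double rad2 = rad * rad;
  for (int col = 0; col < grid; ++col) {
    const double x = col - c;
    for (int row = 0; row < grid; ++row) {
      const double y = row - c;
      out(row, col) = (x * x + y * y > rad2) ? 0.0 : out(row, col) * scale;
    }
  }
  return out;
}

// Separable 2D convolution, valid region only (no padding): output is
// (nr - k + 1) x (nc - k + 1) for a length-k kernel. The kernels used here
// are symmetric so convolution equals correlation.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv_valid(const NumericMatrix& img,
                                const NumericVector& kernel) {
  const int nr = img.nrow(), nc = img.ncol(), k = kernel.size();
  if (k > nr || k > nc) stop("kernel larger than image");
  const int orc = nr - k + 1, occ = nc - k + 1;
  // pass 1: combine columns (axpy over contiguous columns)
  NumericMatrix tmp(nr, occ);
  for (int cc = 0; cc < occ; ++cc) {
    double* tp = &tmp(0, cc);
    for (int j = 0; j < k; ++j) {
      const double w = kernel[j];
      const double* ip = &img(0, cc + j);
      for (int r = 0; r < nr; ++r) tp[r] += w * ip[r];
    }
  }
  // pass 2: combine shifted copies within each column
  NumericMatrix out(orc, occ);
  for (int cc = 0; cc < occ; ++cc) {
    double* op = &out(0, cc);
    const double* tp = &tmp(0, cc);
    for (int j = 0; j < k; ++j) {
      const double w = kernel[j];
      for (int r = 0; r < orc; ++r) op[r] += w * tp[r + j];
    }
  }
  return out;
}
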
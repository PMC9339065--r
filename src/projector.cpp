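// Stacked-2D parallel-beam projector pair.  Pixel-driven with linear
// radial interpolation: voxel (i,j) in slice z contributes
// value * (dx*dy/ds) split linearly over the two radial bins bracketing
// its projected coordinate s = x cos(theta) + y sin(theta).  The back
// projector is the exact transpose, so the pair passes the adjoint test
// to rounding error.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cppForwardProject(NumericVector img, IntegerVector dims,
                                NumericVector vox, NumericVector angles,
                                int nRadial, double ds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles.size();
  const double dx = vox[0], dy = vox[1];
  const double scale = dx * dy / ds;
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double c0 = 0.5 * (nRadial - 1);
  const double *x = REAL(img);
  NumericVector out((R_xlen_t)nRadial * na * nz);
  double *o = REAL(out);
  std::vector<double> xi(nx), yj(ny);
  for (int a = 0; a < na; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    for (int i = 0; i < nx; ++i) xi[i] = (i - cx) * dx * ca;
    for (int j = 0; j < ny; ++j) yj[j] = (j - cy) * dy * sa;
    for (int z = 0; z < nz; ++z) {
      const double *sl = x + (size_t)nx * ny * z;
      double *po = o + (size_t)nRadial * (a + (size_t)na * z);
      for (int j = 0; j < ny; ++j) {
        const double yt = yj[j] / ds + c0;
        const double *row = sl + (size_t)nx * j;
        for (int i = 0; i < nx; ++i) {
          const double v = row[i];
          if (v == 0.0) continue;
          const double p = xi[i] / ds + yt;
          const int b0 = (int)std::floor(p);
          const double f = p - b0;
          if (b0 >= 0 && b0 < nRadial) po[b0] += v * scale * (1.0 - f);
          if (b0 + 1 >= 0 && b0 + 1 < nRadial) po[b0 + 1] += v * scale * f;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cppBackProject(NumericVector proj, IntegerVector dims,
                             NumericVector vox, NumericVector angles,
                             int nRadial, double ds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles.size();
  const double dx = vox[0], dy = vox[1];
  const double scale = dx * dy / ds;
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double c0 = 0.5 * (nRadial - 1);
  const double *pp = REAL(proj);
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *x = REAL(out);
  std::vector<double> xi(nx), yj(ny);
  for (int a = 0; a < na; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    for (int i = 0; i < nx; ++i) xi[i] = (i - cx) * dx * ca;
    for (int j = 0; j < ny; ++j) yj[j] = (j - cy) * dy * sa;
    for (int z = 0; z < nz; ++z) {
      double *sl = x + (size_t)nx * ny * z;
      const double *po = pp + (size_t)nRadial * (a + (size_t)na * z);
      for (int j = 0; j < ny; ++j) {
        const double yt = yj[j] / ds + c0;
        double *row = sl + (size_t)nx * j;
        for (int i = 0; i < nx; ++i) {
          const double p = xi[i] / ds + yt;
          const int b0 = (int)std::floor(p);
          const double f = p - b0;
          double acc = 0.0;
          if (b0 >= 0 && b0 < nRadial) acc += po[b0] * (1.0 - f);
          if (b0 + 1 >= 0 && b0 + 1 < nRadial) acc += po[b0 + 1] * f;
          row[i] += acc * scale;
        }
      }
    }
  }
  return out;
}
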
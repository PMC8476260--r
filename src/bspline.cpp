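#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Free-form deformation: cubic B-spline tensor product over the 4x4x4 control
// points nearest each query point. Control displacements are stored as an R
// array of dim (nx, ny, nz, 3) flattened column-major; query points live in
// the grid's own (axis-aligned, mm) frame.

static inline void ffdWeights(double u, double w[4]) {
  const double u2 = u * u, u3 = u2 * u;
  w[0] = (1.0 - u) * (1.0 - u) * (1.0 - u) / 6.0;
  w[1] = (3.0 * u3 - 6.0 * u2 + 4.0) / 6.0;
  w[2] = (-3.0 * u3 + 3.0 * u2 + 3.0 * u + 1.0) / 6.0;
  w[3] = u3 / 6.0;
}

// [[Rcpp::export]]
List cpp_bspline_disp(NumericVector disp, IntegerVector gshape,
                      NumericVector gorigin, NumericVector gspacing,
                      NumericMatrix pts) {
  const int n = pts.nrow();
  const int nx = gshape[0], ny = gshape[1], nz = gshape[2];
  const long ncp = (long)nx * ny * nz;
  const double *d = disp.begin();
  NumericMatrix out(n, 3);
  LogicalVector indomain(n);
  for (int s = 0; s < n; ++s) {
    double u[3];
    int i0[3];
    bool in = true;
    for (int ax = 0; ax < 3; ++ax) {
      const double r = (pts(s, ax) - gorigin[ax]) / gspacing[ax];
      const double fl = std::floor(r);
      i0[ax] = (int)fl - 1;
      u[ax] = r - fl;
      const int nax = gshape[ax];
      if (i0[ax] < 0 || i0[ax] + 3 > nax - 1) in = false;
    }
    indomain[s] = in;
    if (!in) continue;
    double wx[4], wy[4], wz[4];
    ffdWeights(u[0], wx);
    ffdWeights(u[1], wy);
    ffdWeights(u[2], wz);
    double acc[3] = {0.0, 0.0, 0.0};
    for (int l = 0; l < 4; ++l)
      for (int m = 0; m < 4; ++m) {
        const double wyz = wy[m] * wz[l];
        const long base = (long)nx * ((i0[1] + m) + (long)ny * (i0[2] + l)) + i0[0];
        for (int k = 0; k < 4; ++k) {
          const double w = wx[k] * wyz;
          const long cp = base + k;
          acc[0] += w * d[cp];
          acc[1] += w * d[cp + ncp];
          acc[2] += w * d[cp + 2 * ncp];
        }
      }
    out(s, 0) = acc[0];
    out(s, 1) = acc[1];
    out(s, 2) = acc[2];
  }
  return List::create(_["disp"] = out, _["indomain"] = indomain);
}
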
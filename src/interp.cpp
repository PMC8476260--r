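#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shared low-level sampling kernels. Volumes are stored as R numeric arrays in
// column-major order; all continuous coordinates here are 0-based voxel indices.

static inline int mirrorIndex(int i, int n) {
  // reflect-101 boundary (period 2n-2); safe for any i when n >= 1
  if (n == 1) return 0;
  const int p = 2 * n - 2;
  i = std::abs(i) % p;
  return (i < n) ? i : p - i;
}

static inline void cubicWeights(double u, double w[4]) {
  const double u2 = u * u, u3 = u2 * u;
  w[0] = (1.0 - u) * (1.0 - u) * (1.0 - u) / 6.0;
  w[1] = (3.0 * u3 - 6.0 * u2 + 4.0) / 6.0;
  w[2] = (-3.0 * u3 + 3.0 * u2 + 3.0 * u + 1.0) / 6.0;
  w[3] = u3 / 6.0;
}

static inline double sampleNearest(const double *a, const int *d,
                                   double x, double y, double z, bool &in) {
  const long xi = std::lround(x), yi = std::lround(y), zi = std::lround(z);
  in = xi >= 0 && xi < d[0] && yi >= 0 && yi < d[1] && zi >= 0 && zi < d[2];
  if (!in) return NA_REAL;
  return a[xi + (long)d[0] * (yi + (long)d[1] * zi)];
}

static inline double sampleLinear(const double *a, const int *d,
                                  double x, double y, double z, bool &in) {
  in = x >= 0.0 && x <= d[0] - 1.0 &&
       y >= 0.0 && y <= d[1] - 1.0 &&
       z >= 0.0 && z <= d[2] - 1.0;
  if (!in) return NA_REAL;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > d[0] - 2) x0 = d[0] - 2; if (x0 < 0) x0 = 0;
  if (y0 > d[1] - 2) y0 = d[1] - 2; if (y0 < 0) y0 = 0;
  if (z0 > d[2] - 2) z0 = d[2] - 2; if (z0 < 0) z0 = 0;
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  const long nx = d[0], nxy = (long)d[0] * d[1];
  const double *p = a + x0 + nx * y0 + nxy * z0;
  const double c00 = p[0] + fx * (p[1] - p[0]);
  const double c10 = p[nx] + fx * (p[nx + 1] - p[nx]);
  const double c01 = p[nxy] + fx * (p[nxy + 1] - p[nxy]);
  const double c11 = p[nxy + nx] + fx * (p[nxy + nx + 1] - p[nxy + nx]);
  const double c0 = c00 + fy * (c10 - c00);
  const double c1 = c01 + fy * (c11 - c01);
  return c0 + fz * (c1 - c0);
}

// cubic B-spline reconstruction from a prefiltered coefficient array
static inline double sampleCubic(const double *a, const int *d,
                                 double x, double y, double z, bool &in) {
  in = x >= 0.0 && x <= d[0] - 1.0 &&
       y >= 0.0 && y <= d[1] - 1.0 &&
       z >= 0.0 && z <= d[2] - 1.0;
  if (!in) return NA_REAL;
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double wx[4], wy[4], wz[4];
  cubicWeights(x - x0, wx);
  cubicWeights(y - y0, wy);
  cubicWeights(z - z0, wz);
  int ix[4], iy[4], iz[4];
  for (int k = 0; k < 4; ++k) {
    ix[k] = mirrorIndex(x0 - 1 + k, d[0]);
    iy[k] = mirrorIndex(y0 - 1 + k, d[1]);
    iz[k] = mirrorIndex(z0 - 1 + k, d[2]);
  }
  const long nx = d[0], nxy = (long)d[0] * d[1];
  double v = 0.0;
  for (int kz = 0; kz < 4; ++kz)
    for (int ky = 0; ky < 4; ++ky) {
      const double wyz = wy[ky] * wz[kz];
      const long base = nx * iy[ky] + nxy * iz[kz];
      double row = 0.0;
      for (int kx = 0; kx < 4; ++kx) row += wx[kx] * a[ix[kx] + base];
      v += wyz * row;
    }
  return v;
}

double interp_one(const double *a, const int *d, int method,
                  double x, double y, double z, bool &in) {
  switch (method) {
  case 0: return sampleNearest(a, d, x, y, z, in);
  case 1: return sampleLinear(a, d, x, y, z, in);
  default: return sampleCubic(a, d, x, y, z, in);
  }
}

// [[Rcpp::export]]
List cpp_interp(NumericVector arr, IntegerVector dim, NumericMatrix pts,
                int method, double background) {
  const int n = pts.nrow();
  const double *a = arr.begin();
  int d[3] = {dim[0], dim[1], dim[2]};
  NumericVector out(n);
  LogicalVector indomain(n);
  for (int s = 0; s < n; ++s) {
    bool in;
    double v = interp_one(a, d, method, pts(s, 0), pts(s, 1), pts(s, 2), in);
    indomain[s] = in;
    out[s] = in ? v : background;
  }
  return List::create(_["values"] = out, _["indomain"] = indomain);
}

static void prefilterLine(double *c, int n, long stride) {
  // Unser recursive prefilter for the cubic B-spline, pole z1 = sqrt(3) - 2
  if (n == 1) return;
  const double z = std::sqrt(3.0) - 2.0;
  const double lambda = 6.0;
  for (int i = 0; i < n; ++i) c[i * stride] *= lambda;
  // causal init: truncated z-transform sum with mirror boundary
  int horizon = (int)std::ceil(std::log(1e-14) / std::log(std::fabs(z)));
  double sum = c[0];
  double zn = z;
  for (int k = 1; k < horizon; ++k) {
    sum += zn * c[(long)mirrorIndex(k, n) * stride];
    zn *= z;
  }
  c[0] = sum;
  for (int i = 1; i < n; ++i) c[i * stride] += z * c[(i - 1) * stride];
  // anticausal init
  c[(long)(n - 1) * stride] = (z / (z * z - 1.0)) *
      (c[(long)(n - 1) * stride] + z * c[(long)(n - 2) * stride]);
  for (int i = n - 2; i >= 0; --i)
    c[i * stride] = z * (c[(i + 1) * stride] - c[i * stride]);
}

// [[Rcpp::export]]
NumericVector cpp_bspline_prefilter(NumericVector arr, IntegerVector dim) {
  NumericVector out = clone(arr);
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double *a = out.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      prefilterLine(a + (long)nx * (y + (long)ny * z), nx, 1);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      prefilterLine(a + x + (long)nx * (long)ny * z, ny, nx);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      prefilterLine(a + x + (long)nx * y, nz, (long)nx * ny);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector arr, IntegerVector dim,
                               NumericVector sigma) {
  NumericVector cur = clone(arr);
  const int d[3] = {dim[0], dim[1], dim[2]};
  const long strides[3] = {1, d[0], (long)d[0] * d[1]};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0.0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> w(2 * r + 1);
    double tot = 0.0;
    for (int k = -r; k <= r; ++k) {
      w[k + r] = std::exp(-0.5 * k * k / (s * s));
      tot += w[k + r];
    }
    for (double &x : w) x /= tot;
    NumericVector nxt(cur.size());
    const double *src = cur.begin();
    double *dst = nxt.begin();
    const int n = d[ax];
    const long stride = strides[ax];
    // iterate over all lines along axis ax
    const int oa1 = (ax == 0) ? 1 : 0;
    const int oa2 = (ax == 2) ? 1 : 2;
    for (int j2 = 0; j2 < d[oa2]; ++j2)
      for (int j1 = 0; j1 < d[oa1]; ++j1) {
        const long base = strides[oa1] * j1 + strides[oa2] * j2;
        for (int i = 0; i < n; ++i) {
          double acc = 0.0;
          for (int k = -r; k <= r; ++k)
            acc += w[k + r] * src[base + (long)mirrorIndex(i + k, n) * stride];
          dst[base + (long)i * stride] = acc;
        }
      }
    cur = nxt;
  }
  return cur;
}

// For each row of A, the distance to its nearest neighbour in B (both in mm).
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
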
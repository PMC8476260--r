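#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

double interp_one(const double *a, const int *d, int method,
                  double x, double y, double z, bool &in);

// ---------------------------------------------------------------------------
// Sampled normalized mutual information, Studholme form (H1 + H2) / H12,
// maintained incrementally over a bins x bins joint histogram so that the
// finite-difference gradient of the FFD only pays for the samples a control
// point actually supports.
// ---------------------------------------------------------------------------

static inline double xlogx(int n) { return n > 1 ? n * std::log((double)n) : 0.0; }

struct HistState {
  int B;
  std::vector<int> joint, margF, margM;
  std::vector<double> xt;  // xt[n] = n log n lookup (counts are small ints)
  double Sj, Sf, Sm;
  long N;
  explicit HistState(int bins, int maxcount = 0)
      : B(bins), joint(bins * bins, 0), margF(bins, 0), margM(bins, 0),
        Sj(0), Sf(0), Sm(0), N(0) {
    xt.resize(maxcount + 2);
    for (int n = 0; n < (int)xt.size(); ++n) xt[n] = xlogx(n);
  }
  void add(int fb, int mb) {
    int &j = joint[fb * B + mb];
    Sj += xt[j + 1] - xt[j]; ++j;
    int &f = margF[fb];
    Sf += xt[f + 1] - xt[f]; ++f;
    int &m = margM[mb];
    Sm += xt[m + 1] - xt[m]; ++m;
    ++N;
  }
  void remove(int fb, int mb) {
    int &j = joint[fb * B + mb];
    Sj += xt[j - 1] - xt[j]; --j;
    int &f = margF[fb];
    Sf += xt[f - 1] - xt[f]; --f;
    int &m = margM[mb];
    Sm += xt[m - 1] - xt[m]; --m;
    --N;
  }
  double nmi() const {
    if (N < 2) return NA_REAL;
    const double lN = std::log((double)N);
    const double Hf = lN - Sf / N, Hm = lN - Sm / N, Hj = lN - Sj / N;
    if (Hj <= 1e-12) return 2.0;  // degenerate: single joint cell
    return (Hf + Hm) / Hj;
  }
};

// local inlined trilinear sampler (hot path; mirrors interp.cpp's linear case)
static inline double sampleLin(const double *a, const int *d,
                               double x, double y, double z, bool &in) {
  in = x >= 0.0 && x <= d[0] - 1.0 &&
       y >= 0.0 && y <= d[1] - 1.0 &&
       z >= 0.0 && z <= d[2] - 1.0;
  if (!in) return NA_REAL;
  int x0 = (int)x, y0 = (int)y, z0 = (int)z;
  if (x0 > d[0] - 2) x0 = d[0] - 2;
  if (y0 > d[1] - 2) y0 = d[1] - 2;
  if (z0 > d[2] - 2) z0 = d[2] - 2;
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

static inline int binOf(double v, double lo, double hi, int B) {
  if (hi <= lo) return 0;
  int b = (int)std::floor((v - lo) / (hi - lo) * B);
  if (b < 0) b = 0;
  if (b > B - 1) b = B - 1;
  return b;
}

// ---------------------------------------------------------------------------
// Affine level: stochastic gradient ascent on sampled NMI, central finite
// differences over all 12 parameters (matrix column-major then translation).
// ---------------------------------------------------------------------------

struct SampleSet {
  std::vector<int> fbin;
  std::vector<double> px, py, pz;  // world coordinates of the samples
  int n;
};

static void drawSamples(SampleSet &S, const double *farr, const int *fd,
                        const double *Fiw, const double *fo,
                        double fmin, double fmax, int bins, int nsamp) {
  S.n = nsamp;
  S.fbin.resize(nsamp);
  S.px.resize(nsamp); S.py.resize(nsamp); S.pz.resize(nsamp);
  for (int s = 0; s < nsamp; ++s) {
    int ix = (int)(unif_rand() * fd[0]); if (ix > fd[0] - 1) ix = fd[0] - 1;
    int iy = (int)(unif_rand() * fd[1]); if (iy > fd[1] - 1) iy = fd[1] - 1;
    int iz = (int)(unif_rand() * fd[2]); if (iz > fd[2] - 1) iz = fd[2] - 1;
    const double fv = farr[ix + (long)fd[0] * (iy + (long)fd[1] * iz)];
    S.fbin[s] = binOf(fv, fmin, fmax, bins);
    S.px[s] = Fiw[0] * ix + Fiw[3] * iy + Fiw[6] * iz + fo[0];
    S.py[s] = Fiw[1] * ix + Fiw[4] * iy + Fiw[7] * iz + fo[1];
    S.pz[s] = Fiw[2] * ix + Fiw[5] * iy + Fiw[8] * iz + fo[2];
  }
}

static double nmiAffine(const SampleSet &S, const double *theta,
                        const double *center, const double *marr, const int *md,
                        const double *Mwi, const double *mo,
                        double mmin, double mmax, int bins) {
  HistState H(bins, S.n);
  for (int s = 0; s < S.n; ++s) {
    const double qx = S.px[s] - center[0], qy = S.py[s] - center[1],
                 qz = S.pz[s] - center[2];
    const double yx = theta[0] * qx + theta[3] * qy + theta[6] * qz + center[0] + theta[9];
    const double yy = theta[1] * qx + theta[4] * qy + theta[7] * qz + center[1] + theta[10];
    const double yz = theta[2] * qx + theta[5] * qy + theta[8] * qz + center[2] + theta[11];
    const double mx = Mwi[0] * yx + Mwi[3] * yy + Mwi[6] * yz + mo[0];
    const double my = Mwi[1] * yx + Mwi[4] * yy + Mwi[7] * yz + mo[1];
    const double mz = Mwi[2] * yx + Mwi[5] * yy + Mwi[8] * yz + mo[2];
    bool in;
    const double v = sampleLin(marr, md, mx, my, mz, in);
    if (in) H.add(S.fbin[s], binOf(v, mmin, mmax, bins));
  }
  return H.nmi();
}

// [[Rcpp::export]]
List cpp_register_affine_level(NumericVector farr, IntegerVector fdim,
                               NumericVector marr, IntegerVector mdim,
                               NumericMatrix Fiw, NumericVector fo,
                               NumericMatrix Mwi, NumericVector mo,
                               NumericVector center, NumericVector theta0,
                               int iters, int nsamp, int bins,
                               double fmin, double fmax, double mmin, double mmax,
                               double a, double A, double alpha,
                               NumericVector eps, NumericVector scales) {
  const int fd[3] = {fdim[0], fdim[1], fdim[2]};
  const int md[3] = {mdim[0], mdim[1], mdim[2]};
  std::vector<double> theta(theta0.begin(), theta0.end());
  NumericVector trace(iters);
  SampleSet S;
  double g[12], th[12];
  for (int t = 0; t < iters; ++t) {
    drawSamples(S, farr.begin(), fd, Fiw.begin(), fo.begin(), fmin, fmax,
                bins, nsamp);
    trace[t] = nmiAffine(S, theta.data(), center.begin(), marr.begin(), md,
                         Mwi.begin(), mo.begin(), mmin, mmax, bins);
    double gnorm2 = 0.0;
    for (int k = 0; k < 12; ++k) {
      std::copy(theta.begin(), theta.end(), th);
      th[k] = theta[k] + eps[k];
      const double up = nmiAffine(S, th, center.begin(), marr.begin(), md,
                                  Mwi.begin(), mo.begin(), mmin, mmax, bins);
      th[k] = theta[k] - eps[k];
      const double dn = nmiAffine(S, th, center.begin(), marr.begin(), md,
                                  Mwi.begin(), mo.begin(), mmin, mmax, bins);
      g[k] = (R_finite(up) && R_finite(dn)) ? (up - dn) / (2.0 * eps[k]) : 0.0;
      g[k] *= scales[k];
      gnorm2 += g[k] * g[k];
    }
    const double gnorm = std::sqrt(gnorm2);
    if (gnorm > 1e-12) {
      const double step = a / std::pow(A + t + 1.0, alpha);
      for (int k = 0; k < 12; ++k) theta[k] += step * scales[k] * g[k] / gnorm;
    }
  }
  return List::create(_["theta"] = NumericVector(theta.begin(), theta.end()),
                      _["trace"] = trace);
}

// ---------------------------------------------------------------------------
// B-spline FFD level: the deformation is evaluated at the fixed-image point
// (chain semantics T(x) = Affine(x) + R_f D(aligned(x))), so each sample's
// support weights are fixed within an iteration. The finite-difference
// gradient (over every supported control-point component, or a random subset
// when nsub > 0) updates the joint histogram incrementally over just the
// samples inside each control point's support.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_register_bspline_level(NumericVector farr, IntegerVector fdim,
                                NumericVector fspacing,
                                NumericVector marr, IntegerVector mdim,
                                NumericMatrix Fiw, NumericVector fo,
                                NumericMatrix Mwi, NumericVector mo,
                                NumericVector affTheta, NumericVector affCenter,
                                NumericMatrix Q,
                                NumericVector gorigin, NumericVector gspacing,
                                IntegerVector gshape, NumericVector disp0,
                                int iters, int nsamp, int nsub, int bins,
                                double fmin, double fmax, double mmin, double mmax,
                                double a, double A, double alpha, double eps) {
  const int fd[3] = {fdim[0], fdim[1], fdim[2]};
  const int md[3] = {mdim[0], mdim[1], mdim[2]};
  const int nx = gshape[0], ny = gshape[1], nz = gshape[2];
  const long ncp = (long)nx * ny * nz;
  std::vector<double> disp(disp0.begin(), disp0.end());
  const double *th = affTheta.begin();
  const double *c = affCenter.begin();
  const double *fiw = Fiw.begin(), *mwi = Mwi.begin(), *q = Q.begin();
  NumericVector trace(iters);

  std::vector<int> fbin(nsamp), mbin(nsamp), supX(nsamp), supY(nsamp), supZ(nsamp);
  std::vector<double> wX(nsamp * 4), wY(nsamp * 4), wZ(nsamp * 4);
  std::vector<double> mix(nsamp), miy(nsamp), miz(nsamp);  // current moving index

  for (int t = 0; t < iters; ++t) {
    HistState H(bins, nsamp);
    int nvalid = 0;
    for (int s = 0; s < nsamp; ++s) {
      int iv[3];
      for (int ax = 0; ax < 3; ++ax) {
        int i = (int)(unif_rand() * fd[ax]);
        if (i > fd[ax] - 1) i = fd[ax] - 1;
        iv[ax] = i;
      }
      const double fv = farr[iv[0] + (long)fd[0] * (iv[1] + (long)fd[1] * iv[2])];
      fbin[s] = binOf(fv, fmin, fmax, bins);
      // world point, affine-mapped
      const double px = fiw[0] * iv[0] + fiw[3] * iv[1] + fiw[6] * iv[2] + fo[0];
      const double py = fiw[1] * iv[0] + fiw[4] * iv[1] + fiw[7] * iv[2] + fo[1];
      const double pz = fiw[2] * iv[0] + fiw[5] * iv[1] + fiw[8] * iv[2] + fo[2];
      const double qx = px - c[0], qy = py - c[1], qz = pz - c[2];
      const double yx = th[0] * qx + th[3] * qy + th[6] * qz + c[0] + th[9];
      const double yy = th[1] * qx + th[4] * qy + th[7] * qz + c[1] + th[10];
      const double yz = th[2] * qx + th[5] * qy + th[8] * qz + c[2] + th[11];
      // FFD support at the aligned-frame position of the *fixed* point
      bool inGrid = true;
      double u[3];
      int i0[3];
      const double al[3] = {fspacing[0] * iv[0], fspacing[1] * iv[1],
                            fspacing[2] * iv[2]};
      for (int ax = 0; ax < 3; ++ax) {
        const double r = (al[ax] - gorigin[ax]) / gspacing[ax];
        const double fl = std::floor(r);
        i0[ax] = (int)fl - 1;
        u[ax] = r - fl;
        if (i0[ax] < 0 || i0[ax] + 3 > gshape[ax] - 1) inGrid = false;
      }
      if (!inGrid) { mbin[s] = -2; continue; }  // excluded from this iteration
      supX[s] = i0[0]; supY[s] = i0[1]; supZ[s] = i0[2];
      double u2, u3;
      for (int ax = 0; ax < 3; ++ax) {
        double *w = (ax == 0 ? &wX[s * 4] : ax == 1 ? &wY[s * 4] : &wZ[s * 4]);
        u2 = u[ax] * u[ax]; u3 = u2 * u[ax];
        w[0] = (1 - u[ax]) * (1 - u[ax]) * (1 - u[ax]) / 6.0;
        w[1] = (3 * u3 - 6 * u2 + 4) / 6.0;
        w[2] = (-3 * u3 + 3 * u2 + 3 * u[ax] + 1) / 6.0;
        w[3] = u3 / 6.0;
      }
      // displacement in the aligned frame
      double D[3] = {0, 0, 0};
      for (int l = 0; l < 4; ++l)
        for (int m = 0; m < 4; ++m) {
          const double wyz = wY[s * 4 + m] * wZ[s * 4 + l];
          const long base = (long)nx * ((i0[1] + m) + (long)ny * (i0[2] + l)) + i0[0];
          for (int k = 0; k < 4; ++k) {
            const double w = wX[s * 4 + k] * wyz;
            const long cp = base + k;
            D[0] += w * disp[cp];
            D[1] += w * disp[cp + ncp];
            D[2] += w * disp[cp + 2 * ncp];
          }
        }
      mix[s] = mwi[0] * yx + mwi[3] * yy + mwi[6] * yz + mo[0] +
               q[0] * D[0] + q[3] * D[1] + q[6] * D[2];
      miy[s] = mwi[1] * yx + mwi[4] * yy + mwi[7] * yz + mo[1] +
               q[1] * D[0] + q[4] * D[1] + q[7] * D[2];
      miz[s] = mwi[2] * yx + mwi[5] * yy + mwi[8] * yz + mo[2] +
               q[2] * D[0] + q[5] * D[1] + q[8] * D[2];
      bool in;
      const double v = sampleLin(marr.begin(), md, mix[s], miy[s], miz[s], in);
      if (in) {
        mbin[s] = binOf(v, mmin, mmax, bins);
        H.add(fbin[s], mbin[s]);
        ++nvalid;
      } else {
        mbin[s] = -1;
      }
    }
    trace[t] = H.nmi();
    if (nvalid < bins) continue;  // too little overlap to estimate a gradient

    // control points to differentiate: by default every one with support
    // among this iteration's samples; optionally (nsub > 0) a random subset.
    // All three axis components of a control point share the same affected
    // samples and weights, so the lists are built once per control point.
    std::vector<int> slotCp(ncp, -1);
    std::vector<long> pcp;
    if (nsub > 0) {
      int tries = 0;
      while ((int)pcp.size() < nsub && tries < nsub * 8) {
        ++tries;
        int s = (int)(unif_rand() * nsamp);
        if (s > nsamp - 1) s = nsamp - 1;
        if (mbin[s] == -2) continue;
        const int k = (int)(unif_rand() * 4) & 3;
        const int m = (int)(unif_rand() * 4) & 3;
        const int l = (int)(unif_rand() * 4) & 3;
        const long cp = (supX[s] + k) +
                        (long)nx * ((supY[s] + m) + (long)ny * (supZ[s] + l));
        if (slotCp[cp] >= 0) continue;
        slotCp[cp] = (int)pcp.size();
        pcp.push_back(cp);
      }
    } else {
      for (int s = 0; s < nsamp; ++s) {
        if (mbin[s] == -2) continue;
        for (int l = 0; l < 4; ++l)
          for (int m = 0; m < 4; ++m) {
            const long base = (long)nx * ((supY[s] + m) + (long)ny * (supZ[s] + l)) + supX[s];
            for (int k = 0; k < 4; ++k) {
              const long cp = base + k;
              if (slotCp[cp] < 0) {
                slotCp[cp] = (int)pcp.size();
                pcp.push_back(cp);
              }
            }
          }
      }
    }
    const int ncps = (int)pcp.size();
    if (ncps == 0) continue;

    // CSR layout of (sample, weight) lists per chosen control point
    // entries with negligible weight cannot move a sample across an
    // intensity bin for any reasonable eps; drop them from the gradient
    const double wcut = 0.01;
    std::vector<int> cnt(ncps, 0);
    for (int s = 0; s < nsamp; ++s) {
      if (mbin[s] == -2) continue;
      for (int l = 0; l < 4; ++l)
        for (int m = 0; m < 4; ++m) {
          const long base = (long)nx * ((supY[s] + m) + (long)ny * (supZ[s] + l)) + supX[s];
          const double wyz = wY[s * 4 + m] * wZ[s * 4 + l];
          for (int k = 0; k < 4; ++k) {
            const int sl = slotCp[base + k];
            if (sl >= 0 && wX[s * 4 + k] * wyz > wcut) ++cnt[sl];
          }
        }
    }
    std::vector<int> off(ncps + 1, 0);
    for (int i = 0; i < ncps; ++i) off[i + 1] = off[i] + cnt[i];
    std::vector<int> sidx(off[ncps]);
    std::vector<double> swt(off[ncps]);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int s = 0; s < nsamp; ++s) {
      if (mbin[s] == -2) continue;
      for (int l = 0; l < 4; ++l)
        for (int m = 0; m < 4; ++m) {
          const long base = (long)nx * ((supY[s] + m) + (long)ny * (supZ[s] + l)) + supX[s];
          const double wyz = wY[s * 4 + m] * wZ[s * 4 + l];
          for (int k = 0; k < 4; ++k) {
            const int sl = slotCp[base + k];
            if (sl < 0) continue;
            const double w = wX[s * 4 + k] * wyz;
            if (w <= wcut) continue;
            const int pos = off[sl] + cnt[sl]++;
            sidx[pos] = s;
            swt[pos] = w;
          }
        }
    }

    std::vector<double> g(3 * ncps, 0.0);
    std::vector<std::pair<int, int> > undo;
    undo.reserve(256);
    for (int pi = 0; pi < ncps; ++pi) {
      for (int ax = 0; ax < 3; ++ax) {
        const double qx = q[0 + ax * 3], qy = q[1 + ax * 3], qz = q[2 + ax * 3];
        double val[2];
        for (int dir = 0; dir < 2; ++dir) {  // central differences: +eps, -eps
          const double delta = dir == 0 ? eps : -eps;
          undo.clear();
          for (int pos = off[pi]; pos < off[pi + 1]; ++pos) {
            const int s = sidx[pos];
            const double dd = delta * swt[pos];
            bool in;
            const double v = sampleLin(marr.begin(), md,
                                       mix[s] + qx * dd, miy[s] + qy * dd,
                                       miz[s] + qz * dd, in);
            const int nb = in ? binOf(v, mmin, mmax, bins) : -1;
            if (nb == mbin[s]) continue;
            if (mbin[s] >= 0) H.remove(fbin[s], mbin[s]);
            if (nb >= 0) H.add(fbin[s], nb);
            undo.push_back(std::make_pair(s, mbin[s]));
            mbin[s] = nb;
          }
          val[dir] = H.nmi();
          for (int ui = (int)undo.size() - 1; ui >= 0; --ui) {
            const int s = undo[ui].first, ob = undo[ui].second;
            if (mbin[s] >= 0) H.remove(fbin[s], mbin[s]);
            if (ob >= 0) H.add(fbin[s], ob);
            mbin[s] = ob;
          }
        }
        g[3 * pi + ax] = (R_finite(val[0]) && R_finite(val[1]))
                             ? (val[0] - val[1]) / (2.0 * eps) : 0.0;
      }
    }
    // max-norm step: the strongest component moves by the full step length
    double gmax = 0.0;
    for (size_t i = 0; i < g.size(); ++i)
      if (std::fabs(g[i]) > gmax) gmax = std::fabs(g[i]);
    if (gmax > 1e-12) {
      const double step = a / std::pow(A + t + 1.0, alpha);
      for (int pi = 0; pi < ncps; ++pi)
        for (int ax = 0; ax < 3; ++ax)
          disp[pcp[pi] + ncp * ax] += step * g[3 * pi + ax] / gmax;
    }
  }
  return List::create(_["disp"] = NumericVector(disp.begin(), disp.end()),
                      _["trace"] = trace);
}
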
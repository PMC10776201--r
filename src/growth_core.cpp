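// Numerical core: Euclidean distance transforms, trilinear sampling,
// cubic B-spline free-form deformation (value + SSD gradient), and an
// analytic symmetric 3x3 eigensolver for tensor fields.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ----------------------------------------------------------------------------
// 1D lower-envelope squared distance transform (Felzenszwalb & Huttenlocher),
// generalized to sample spacing h (mm).  f holds squared distances at the
// samples; d receives the transformed values.
// ----------------------------------------------------------------------------
static void dt1d(const double* f, double* d, int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF && f[v[k]] == INF) { // both empty: parabola never wins
      // treat as a very high parabola; push only if current envelope is empty
      if (k == 0 && f[v[0]] == INF) { v[0] = q; continue; }
    }
    double s;
    while (true) {
      int p = v[k];
      double fq = f[q], fp = f[p];
      if (fq == INF) { s = INF; break; }
      if (fp == INF) { s = -INF; }
      else {
        s = (fq - fp + h * h * (double)(q * q - p * p)) / (2.0 * h * (q - p));
      }
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s == INF) continue; // f[q] infinite: never part of envelope
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double x = h * q;
    while (z[k + 1] < x) ++k;
    double dx = x - h * v[k];
    double fv = f[v[k]];
    d[q] = (fv == INF) ? INF : dx * dx + fv;
  }
}

// Squared Euclidean distance (mm^2) to the nearest TRUE voxel centre.
// [[Rcpp::export]]
NumericVector cpp_edt2(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      double* row = &out[(R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      for (int x = 0; x < nx; ++x) f[x] = row[x];
      dt1d(f.data(), d.data(), nx, spacing[0]);
      for (int x = 0; x < nx; ++x) row[x] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      dt1d(f.data(), d.data(), ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = d[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
      dt1d(f.data(), d.data(), nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = d[z];
    }
  return out;
}

// ----------------------------------------------------------------------------
// Trilinear sampling with clamped borders (coords are 0-based voxel indices)
// ----------------------------------------------------------------------------
static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double tri_sample(const double* vol, int nx, int ny, int nz,
                                double x, double y, double z) {
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int x0 = (int)std::floor(x); if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  int y0 = (int)std::floor(y); if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  int z0 = (int)std::floor(z); if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const double* p = vol + x0 * sx + y0 * sy + z0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// value + analytic gradient (per voxel unit) of the trilinear interpolant
static inline double tri_sample_grad(const double* vol, int nx, int ny, int nz,
                                     double x, double y, double z, double g[3]) {
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int x0 = (int)std::floor(x); if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  int y0 = (int)std::floor(y); if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  int z0 = (int)std::floor(z); if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const double* p = vol + x0 * sx + y0 * sy + z0 * sz;
  double v000 = p[0], v100 = p[sx], v010 = p[sy], v110 = p[sy + sx];
  double v001 = p[sz], v101 = p[sz + sx], v011 = p[sz + sy], v111 = p[sz + sy + sx];
  double c00 = v000 * (1 - fx) + v100 * fx;
  double c10 = v010 * (1 - fx) + v110 * fx;
  double c01 = v001 * (1 - fx) + v101 * fx;
  double c11 = v011 * (1 - fx) + v111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  g[0] = ((v100 - v000) * (1 - fy) + (v110 - v010) * fy) * (1 - fz)
       + ((v101 - v001) * (1 - fy) + (v111 - v011) * fy) * fz;
  g[1] = (c10 - c00) * (1 - fz) + (c11 - c01) * fz;
  g[2] = c1 - c0;
  return c0 * (1 - fz) + c1 * fz;
}

// Sample a 3D volume at arbitrary 0-based voxel coordinates.
// mode 0 = trilinear (clamped), 1 = nearest neighbour; points outside the
// grid by more than `pad` voxels get `outside`.
// [[Rcpp::export]]
NumericVector cpp_sample_points(NumericVector vol, IntegerVector dim,
                                NumericMatrix pts, int mode, double outside,
                                double pad) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double* v = REAL(vol);
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (x < -pad || y < -pad || z < -pad ||
        x > nx - 1 + pad || y > ny - 1 + pad || z > nz - 1 + pad) {
      out[i] = outside;
      continue;
    }
    if (mode == 1) {
      int xi = (int)std::lround(clampd(x, 0, nx - 1.0));
      int yi = (int)std::lround(clampd(y, 0, ny - 1.0));
      int zi = (int)std::lround(clampd(z, 0, nz - 1.0));
      out[i] = v[xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
    } else {
      out[i] = tri_sample(v, nx, ny, nz, x, y, z);
    }
  }
  return out;
}

// Mean squared intensity difference between fixed and moving resampled
// through the 4x4 voxel-to-voxel map M (fixed voxel -> moving voxel).
// Voxels mapping outside the moving grid are skipped; returns Inf when the
// overlap drops below a quarter of the sampled voxels.
// [[Rcpp::export]]
double cpp_affine_ssd(NumericVector mov, IntegerVector mdim,
                      NumericVector fix, IntegerVector fdim,
                      NumericMatrix M, int stride) {
  const int mx = mdim[0], my = mdim[1], mz = mdim[2];
  const int fx = fdim[0], fy = fdim[1], fz = fdim[2];
  const double* mv = REAL(mov);
  const double* fv = REAL(fix);
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  double ss = 0.0;
  R_xlen_t cnt = 0, tot = 0;
  for (int z = 0; z < fz; z += stride)
    for (int y = 0; y < fy; y += stride)
      for (int x = 0; x < fx; x += stride) {
        ++tot;
        double px = m00 * x + m01 * y + m02 * z + m03;
        double py = m10 * x + m11 * y + m12 * z + m13;
        double pz = m20 * x + m21 * y + m22 * z + m23;
        if (px < 0 || py < 0 || pz < 0 ||
            px > mx - 1 || py > my - 1 || pz > mz - 1) continue;
        double d = tri_sample(mv, mx, my, mz, px, py, pz)
                 - fv[x + (R_xlen_t)fx * (y + (R_xlen_t)fy * z)];
        ss += d * d;
        ++cnt;
      }
  if (cnt < tot / 4 || cnt == 0) {
    // losing overlap must be costly but finite so finite-difference
    // gradients stay usable
    double frac = tot > 0 ? (double)cnt / (double)tot : 0.0;
    return 1e8 * (2.0 - frac);
  }
  return ss / (double)cnt;
}

// ----------------------------------------------------------------------------
// Cubic B-spline free-form deformation on a control-point lattice.
// Control point i corresponds to lattice position (i - 1) * delta in voxel
// units, so a voxel at coordinate x uses control indices floor(x/delta)+0..3.
// ----------------------------------------------------------------------------
static inline void bsp_w(double s, double* w) {
  double s2 = s * s, s3 = s2 * s;
  w[0] = (1.0 - 3.0 * s + 3.0 * s2 - s3) / 6.0;
  w[1] = (4.0 - 6.0 * s2 + 3.0 * s3) / 6.0;
  w[2] = (1.0 + 3.0 * s + 3.0 * s2 - 3.0 * s3) / 6.0;
  w[3] = s3 / 6.0;
}

struct AxisTab { std::vector<int> b; std::vector<double> w; };

static AxisTab axis_table(int n, double delta) {
  AxisTab t;
  t.b.resize(n);
  t.w.resize(4 * (R_xlen_t)n);
  for (int x = 0; x < n; ++x) {
    double u = x / delta;
    int b = (int)std::floor(u);
    double s = u - b;
    t.b[x] = b;
    bsp_w(s, &t.w[4 * (R_xlen_t)x]);
  }
  return t;
}

// SSD + bending-energy cost and (optionally) its gradient w.r.t. the control
// displacements.  All quantities in voxel units of the working grid.
// [[Rcpp::export]]
List cpp_ffd_cost_grad(NumericVector cp, IntegerVector cpdim,
                       NumericVector fixv, NumericVector movv,
                       IntegerVector dim, NumericVector delta,
                       IntegerVector active, double lambda, bool want_grad) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int cx = cpdim[0], cy = cpdim[1], cz = cpdim[2];
  const R_xlen_t ncp = (R_xlen_t)cx * cy * cz;
  const double* cpv = REAL(cp);
  const double* fv = REAL(fixv);
  const double* mv = REAL(movv);
  const int na = active.size();

  AxisTab tx = axis_table(nx, delta[0]);
  AxisTab ty = axis_table(ny, delta[1]);
  AxisTab tz = axis_table(nz, delta[2]);

  NumericVector grad(want_grad ? cp.size() : 0);
  double* gv = want_grad ? REAL(grad) : nullptr;
  double cost = 0.0;

  for (int a = 0; a < na; ++a) {
    R_xlen_t idx = (R_xlen_t)active[a];
    int x = (int)(idx % nx);
    R_xlen_t rem = idx / nx;
    int y = (int)(rem % ny);
    int z = (int)(rem / ny);
    const double* wx = &tx.w[4 * (R_xlen_t)x];
    const double* wy = &ty.w[4 * (R_xlen_t)y];
    const double* wz = &tz.w[4 * (R_xlen_t)z];
    const int bx = tx.b[x], by = ty.b[y], bz = tz.b[z];

    double u0 = 0, u1 = 0, u2 = 0;
    double wgt[64];
    int cidx[64];
    int q = 0;
    for (int n3 = 0; n3 < 4; ++n3) {
      R_xlen_t off_z = (R_xlen_t)(bz + n3) * cx * cy;
      double wzz = wz[n3];
      for (int n2 = 0; n2 < 4; ++n2) {
        R_xlen_t off_yz = off_z + (R_xlen_t)(by + n2) * cx;
        double wyz = wy[n2] * wzz;
        for (int n1 = 0; n1 < 4; ++n1) {
          double w = wx[n1] * wyz;
          R_xlen_t ci = off_yz + (bx + n1);
          wgt[q] = w;
          cidx[q] = (int)ci;
          u0 += w * cpv[ci];
          u1 += w * cpv[ci + ncp];
          u2 += w * cpv[ci + 2 * ncp];
          ++q;
        }
      }
    }

    double g[3];
    double m = want_grad
      ? tri_sample_grad(mv, nx, ny, nz, x + u0, y + u1, z + u2, g)
      : tri_sample(mv, nx, ny, nz, x + u0, y + u1, z + u2);
    double r = m - fv[idx];
    cost += r * r;
    if (want_grad) {
      double f0 = 2.0 * r * g[0], f1 = 2.0 * r * g[1], f2 = 2.0 * r * g[2];
      for (int k = 0; k < 64; ++k) {
        double w = wgt[k];
        R_xlen_t ci = cidx[k];
        gv[ci] += w * f0;
        gv[ci + ncp] += w * f1;
        gv[ci + 2 * ncp] += w * f2;
      }
    }
  }

  double inv_na = na > 0 ? 1.0 / (double)na : 0.0;
  cost *= inv_na;
  if (want_grad) for (R_xlen_t i = 0; i < (R_xlen_t)grad.size(); ++i) gv[i] *= inv_na;

  // bending proxy: squared second differences of the control lattice
  if (lambda > 0) {
    double eb = 0.0;
    R_xlen_t nterms = 0;
    const int strides[3] = {1, cx, cx * cy};
    const int dims[3] = {cx, cy, cz};
    for (int c = 0; c < 3; ++c) {
      const double* comp = cpv + (R_xlen_t)c * ncp;
      for (int ax = 0; ax < 3; ++ax) {
        int st = strides[ax];
        for (int k = 0; k < cz; ++k)
          for (int j = 0; j < cy; ++j)
            for (int i = 0; i < cx; ++i) {
              int pos[3] = {i, j, k};
              if (pos[ax] < 1 || pos[ax] > dims[ax] - 2) continue;
              R_xlen_t ci = i + (R_xlen_t)cx * (j + (R_xlen_t)cy * k);
              double dd = comp[ci - st] - 2.0 * comp[ci] + comp[ci + st];
              eb += dd * dd;
              ++nterms;
            }
      }
    }
    double inv_nt = nterms > 0 ? 1.0 / (double)nterms : 0.0;
    cost += lambda * eb * inv_nt;
    if (want_grad && nterms > 0) {
      double sc = 2.0 * lambda * inv_nt;
      for (int c = 0; c < 3; ++c) {
        const double* comp = cpv + (R_xlen_t)c * ncp;
        double* gc = gv + (R_xlen_t)c * ncp;
        for (int ax = 0; ax < 3; ++ax) {
          int st = strides[ax];
          for (int k = 0; k < cz; ++k)
            for (int j = 0; j < cy; ++j)
              for (int i = 0; i < cx; ++i) {
                int pos[3] = {i, j, k};
                if (pos[ax] < 1 || pos[ax] > dims[ax] - 2) continue;
                R_xlen_t ci = i + (R_xlen_t)cx * (j + (R_xlen_t)cy * k);
                double dd = comp[ci - st] - 2.0 * comp[ci] + comp[ci + st];
                gc[ci - st] += sc * dd;
                gc[ci]     -= 2.0 * sc * dd;
                gc[ci + st] += sc * dd;
              }
        }
      }
    }
  }

  if (want_grad) return List::create(_["cost"] = cost, _["grad"] = grad);
  return List::create(_["cost"] = cost);
}

// Dense displacement field (voxel units) from a control grid; returns a
// vector of length nx*ny*nz*3 in R array order (x fastest, component last).
// [[Rcpp::export]]
NumericVector cpp_ffd_field(NumericVector cp, IntegerVector cpdim,
                            IntegerVector dim, NumericVector delta) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int cx = cpdim[0], cy = cpdim[1], cz = cpdim[2];
  const R_xlen_t ncp = (R_xlen_t)cx * cy * cz;
  const R_xlen_t nv = (R_xlen_t)nx * ny * nz;
  const double* cpv = REAL(cp);
  NumericVector out(nv * 3);
  double* ov = REAL(out);

  AxisTab tx = axis_table(nx, delta[0]);
  AxisTab ty = axis_table(ny, delta[1]);
  AxisTab tz = axis_table(nz, delta[2]);

  R_xlen_t idx = 0;
  for (int z = 0; z < nz; ++z) {
    const double* wz = &tz.w[4 * (R_xlen_t)z];
    int bz = tz.b[z];
    for (int y = 0; y < ny; ++y) {
      const double* wy = &ty.w[4 * (R_xlen_t)y];
      int by = ty.b[y];
      for (int x = 0; x < nx; ++x, ++idx) {
        const double* wx = &tx.w[4 * (R_xlen_t)x];
        int bx = tx.b[x];
        double u0 = 0, u1 = 0, u2 = 0;
        for (int n3 = 0; n3 < 4; ++n3) {
          R_xlen_t off_z = (R_xlen_t)(bz + n3) * cx * cy;
          for (int n2 = 0; n2 < 4; ++n2) {
            R_xlen_t off = off_z + (R_xlen_t)(by + n2) * cx + bx;
            double wzy = wz[n3] * wy[n2];
            for (int n1 = 0; n1 < 4; ++n1) {
              double w = wx[n1] * wzy;
              u0 += w * cpv[off + n1];
              u1 += w * cpv[off + n1 + ncp];
              u2 += w * cpv[off + n1 + 2 * ncp];
            }
          }
        }
        ov[idx] = u0;
        ov[idx + nv] = u1;
        ov[idx + 2 * nv] = u2;
      }
    }
  }
  return out;
}

// Evaluate the FFD displacement at arbitrary 0-based voxel coordinates
// (used to seed the next multi-resolution level).
// [[Rcpp::export]]
NumericMatrix cpp_ffd_eval_points(NumericVector cp, IntegerVector cpdim,
                                  NumericVector delta, NumericMatrix pts) {
  const int cx = cpdim[0], cy = cpdim[1], cz = cpdim[2];
  const R_xlen_t ncp = (R_xlen_t)cx * cy * cz;
  const double* cpv = REAL(cp);
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  double w1[4], w2[4], w3[4];
  for (int i = 0; i < n; ++i) {
    double ux = pts(i, 0) / delta[0];
    double uy = pts(i, 1) / delta[1];
    double uz = pts(i, 2) / delta[2];
    int bx = (int)std::floor(ux), by = (int)std::floor(uy), bz = (int)std::floor(uz);
    // clamp so the 4-neighbourhood stays inside the lattice
    if (bx < 0) bx = 0; if (bx > cx - 4) bx = cx - 4;
    if (by < 0) by = 0; if (by > cy - 4) by = cy - 4;
    if (bz < 0) bz = 0; if (bz > cz - 4) bz = cz - 4;
    bsp_w(ux - bx, w1);
    bsp_w(uy - by, w2);
    bsp_w(uz - bz, w3);
    double u0 = 0, u1 = 0, u2 = 0;
    for (int n3 = 0; n3 < 4; ++n3)
      for (int n2 = 0; n2 < 4; ++n2)
        for (int n1 = 0; n1 < 4; ++n1) {
          double w = w1[n1] * w2[n2] * w3[n3];
          R_xlen_t ci = (bx + n1) + (R_xlen_t)cx * ((by + n2) + (R_xlen_t)cy * (bz + n3));
          u0 += w * cpv[ci];
          u1 += w * cpv[ci + ncp];
          u2 += w * cpv[ci + 2 * ncp];
        }
    out(i, 0) = u0; out(i, 1) = u1; out(i, 2) = u2;
  }
  return out;
}

// ----------------------------------------------------------------------------
// Analytic eigendecomposition of symmetric 3x3 tensors (n x 6, order
// xx, xy, xz, yy, yz, zz).  Returns eigenvalues sorted descending and the
// unit eigenvector of the largest eigenvalue (NaN when numerically
// degenerate; validity gating happens in R).
// ----------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_eig3_principal(NumericMatrix tens) {
  const int n = tens.nrow();
  NumericMatrix evals(n, 3);
  NumericMatrix evec(n, 3);
  for (int i = 0; i < n; ++i) {
    double a11 = tens(i, 0), a12 = tens(i, 1), a13 = tens(i, 2);
    double a22 = tens(i, 3), a23 = tens(i, 4), a33 = tens(i, 5);
    double p1 = a12 * a12 + a13 * a13 + a23 * a23;
    double l1, l2, l3;
    if (p1 == 0.0) {
      // already diagonal
      l1 = a11; l2 = a22; l3 = a33;
      double v[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
      int ord[3] = {0, 1, 2};
      double lv[3] = {l1, l2, l3};
      // sort descending
      for (int a = 0; a < 2; ++a)
        for (int b = a + 1; b < 3; ++b)
          if (lv[ord[b]] > lv[ord[a]]) std::swap(ord[a], ord[b]);
      evals(i, 0) = lv[ord[0]]; evals(i, 1) = lv[ord[1]]; evals(i, 2) = lv[ord[2]];
      evec(i, 0) = v[ord[0]][0]; evec(i, 1) = v[ord[0]][1]; evec(i, 2) = v[ord[0]][2];
      continue;
    }
    double q = (a11 + a22 + a33) / 3.0;
    double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q)
              + (a33 - q) * (a33 - q) + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    double b11 = (a11 - q) / p, b12 = a12 / p, b13 = a13 / p;
    double b22 = (a22 - q) / p, b23 = a23 / p, b33 = (a33 - q) / p;
    double detB = b11 * (b22 * b33 - b23 * b23)
                - b12 * (b12 * b33 - b23 * b13)
                + b13 * (b12 * b23 - b22 * b13);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    double phi = std::acos(r) / 3.0;
    l1 = q + 2.0 * p * std::cos(phi);
    l3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    l2 = 3.0 * q - l1 - l3;
    // Newton-polish the roots of the characteristic polynomial: acos loses
    // ~sqrt(eps) near degenerate tensors, and the projector eigenvector
    // below inherits eigenvalue error divided by the eigen gap
    {
      double tr = a11 + a22 + a33;
      double m2 = a11 * a22 + a11 * a33 + a22 * a33
                - a12 * a12 - a13 * a13 - a23 * a23;
      double dt = a11 * (a22 * a33 - a23 * a23)
                - a12 * (a12 * a33 - a23 * a13)
                + a13 * (a12 * a23 - a22 * a13);
      double* ls[3] = {&l1, &l2, &l3};
      double sc = std::fabs(l1) + std::fabs(l2) + std::fabs(l3) + 1e-300;
      for (int k = 0; k < 3; ++k)
        for (int it = 0; it < 2; ++it) {
          double lv = *ls[k];
          double f = ((lv - tr) * lv + m2) * lv - dt;
          double df = (3.0 * lv - 2.0 * tr) * lv + m2;
          if (std::fabs(df) < 1e-300) continue;
          double step = f / df;
          // at (near-)double roots f and df are both ~eps and their ratio
          // is garbage; real polishing steps are tiny relative to scale
          if (std::fabs(step) < 1e-6 * sc) *ls[k] = lv - step;
        }
      if (l2 > l1) std::swap(l1, l2);
      if (l3 > l2) { std::swap(l2, l3); if (l2 > l1) std::swap(l1, l2); }
    }
    evals(i, 0) = l1; evals(i, 1) = l2; evals(i, 2) = l3;

    // eigenvector of l1 from columns of (A - l2 I)(A - l3 I)
    double c2[3][3] = {{a11 - l2, a12, a13}, {a12, a22 - l2, a23}, {a13, a23, a33 - l2}};
    double c3[3][3] = {{a11 - l3, a12, a13}, {a12, a22 - l3, a23}, {a13, a23, a33 - l3}};
    double best[3] = {0, 0, 0};
    double bestn = -1.0;
    for (int col = 0; col < 3; ++col) {
      double v0 = c2[0][0] * c3[0][col] + c2[0][1] * c3[1][col] + c2[0][2] * c3[2][col];
      double v1 = c2[1][0] * c3[0][col] + c2[1][1] * c3[1][col] + c2[1][2] * c3[2][col];
      double v2 = c2[2][0] * c3[0][col] + c2[2][1] * c3[1][col] + c2[2][2] * c3[2][col];
      double nn = v0 * v0 + v1 * v1 + v2 * v2;
      if (nn > bestn) { bestn = nn; best[0] = v0; best[1] = v1; best[2] = v2; }
    }
    double scale = std::sqrt(a11 * a11 + a22 * a22 + a33 * a33 + 2.0 * p1);
    double den = scale * scale; // typical magnitude of the product's entries
    if (bestn > 1e-24 * den * den) {
      double nn = std::sqrt(bestn);
      double v0 = best[0] / nn, v1 = best[1] / nn, v2 = best[2] / nn;
      // two refinement passes through the projector sharpen the direction
      // (each pass multiplies the error by the eigenvalue separation ratio)
      for (int it = 0; it < 2; ++it) {
        double t0 = c3[0][0] * v0 + c3[0][1] * v1 + c3[0][2] * v2;
        double t1 = c3[1][0] * v0 + c3[1][1] * v1 + c3[1][2] * v2;
        double t2 = c3[2][0] * v0 + c3[2][1] * v1 + c3[2][2] * v2;
        double w0 = c2[0][0] * t0 + c2[0][1] * t1 + c2[0][2] * t2;
        double w1 = c2[1][0] * t0 + c2[1][1] * t1 + c2[1][2] * t2;
        double w2 = c2[2][0] * t0 + c2[2][1] * t1 + c2[2][2] * t2;
        double wn = std::sqrt(w0 * w0 + w1 * w1 + w2 * w2);
        if (wn < 1e-30) break;
        v0 = w0 / wn; v1 = w1 / wn; v2 = w2 / wn;
      }
      evec(i, 0) = v0; evec(i, 1) = v1; evec(i, 2) = v2;
    } else {
      evec(i, 0) = NA_REAL; evec(i, 1) = NA_REAL; evec(i, 2) = NA_REAL;
    }
  }
  return List::create(_["values"] = evals, _["vector"] = evec);
}
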
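#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// Column-major 3D indexing helper. All voxel coordinates are 0-based,
// voxel-center convention.
static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// ---------------------------------------------------------------------------
// Trilinear / nearest sampling at continuous 0-based voxel coordinates.
// Out-of-support coordinates return `fill`. The lerp hits its endpoints
// exactly so that on-lattice queries reproduce stored values bit-exactly.
// ---------------------------------------------------------------------------

static inline double lerp1(double a, double b, double t) {
  if (t <= 0.0) return a;
  if (t >= 1.0) return b;
  return a + t * (b - a);
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector arr, IntegerVector dim,
                                   NumericVector cx, NumericVector cy,
                                   NumericVector cz, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = cx.size();
  NumericVector out(n);
  const double *a = arr.begin();
  for (R_xlen_t t = 0; t < n; ++t) {
    double x = cx[t], y = cy[t], z = cz[t];
    if (!R_finite(x) || !R_finite(y) || !R_finite(z) ||
        x < 0.0 || y < 0.0 || z < 0.0 ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
      out[t] = fill;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double c000 = a[idx3(i0, j0, k0, nx, ny)], c100 = a[idx3(i1, j0, k0, nx, ny)];
    double c010 = a[idx3(i0, j1, k0, nx, ny)], c110 = a[idx3(i1, j1, k0, nx, ny)];
    double c001 = a[idx3(i0, j0, k1, nx, ny)], c101 = a[idx3(i1, j0, k1, nx, ny)];
    double c011 = a[idx3(i0, j1, k1, nx, ny)], c111 = a[idx3(i1, j1, k1, nx, ny)];
    double c00 = lerp1(c000, c100, fx);
    double c10 = lerp1(c010, c110, fx);
    double c01 = lerp1(c001, c101, fx);
    double c11 = lerp1(c011, c111, fx);
    double c0 = lerp1(c00, c10, fy);
    double c1 = lerp1(c01, c11, fy);
    out[t] = lerp1(c0, c1, fz);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_nearest(NumericVector arr, IntegerVector dim,
                                 NumericVector cx, NumericVector cy,
                                 NumericVector cz, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = cx.size();
  NumericVector out(n);
  const double *a = arr.begin();
  for (R_xlen_t t = 0; t < n; ++t) {
    double x = cx[t], y = cy[t], z = cz[t];
    if (!R_finite(x) || !R_finite(y) || !R_finite(z) ||
        x < -0.5 || y < -0.5 || z < -0.5 ||
        x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) {
      out[t] = fill;
      continue;
    }
    int i = (int)std::floor(x + 0.5), j = (int)std::floor(y + 0.5),
        k = (int)std::floor(z + 0.5);
    i = std::max(0, std::min(i, nx - 1));
    j = std::max(0, std::min(j, ny - 1));
    k = std::max(0, std::min(k, nz - 1));
    out[t] = a[idx3(i, j, k, nx, ny)];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// anisotropic spacing in mm. Input: mask (1 = feature). Output: squared
// distance in mm^2 from every voxel to the nearest feature voxel.
// ---------------------------------------------------------------------------

static void edt_1d(const std::vector<double> &f, std::vector<double> &d,
                   int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  // lower envelope of parabolas at positions i*s with heights f[i];
  // +Inf heights (no feature reachable yet) are never envelope members
  int q0 = 0;
  while (q0 < n && !R_finite(f[q0])) q0++;
  if (q0 == n) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (!R_finite(f[q])) continue;
    double qs = q * s;
    double sint;
    while (true) {
      double vs = v[k] * s;
      sint = ((f[q] + qs * qs) - (f[v[k]] + vs * vs)) / (2.0 * qs - 2.0 * vs);
      if (sint <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = INF;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * s;
    while (z[kk + 1] < qs) kk++;
    double vs = v[kk] * s;
    d[q] = (qs - vs) * (qs - vs) + f[v[kk]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = mask[t] ? 0.0 : INF;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      bool any = false;
      for (int i = 0; i < nx; ++i) {
        f[i] = out[idx3(i, j, k, nx, ny)];
        if (f[i] == 0.0) any = true;
      }
      if (!any) continue;  // stays +Inf along this line until later passes
      edt_1d(f, d, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[idx3(i, j, k, nx, ny)] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      bool any = false;
      for (int j = 0; j < ny; ++j) {
        f[j] = out[idx3(i, j, k, nx, ny)];
        if (R_finite(f[j])) any = true;
      }
      if (!any) continue;
      edt_1d(f, d, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[idx3(i, j, k, nx, ny)] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      bool any = false;
      for (int k = 0; k < nz; ++k) {
        f[k] = out[idx3(i, j, k, nx, ny)];
        if (R_finite(f[k])) any = true;
      }
      if (!any) continue;
      edt_1d(f, d, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) out[idx3(i, j, k, nx, ny)] = d[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Cubic B-spline free-form deformation: dense evaluation and SSD cost +
// analytic gradient with respect to the control-point displacements.
// Control grid: origin_vox (0-based voxel units, may be fractional),
// spacing_vox per axis; coefficient c[i,j,k] multiplies
// B3((x - origin)/spacing - (i-1)) etc., i in 0..nc-1.
// ---------------------------------------------------------------------------

static inline void bspline_w(double t, double *w) {
  // cubic B-spline basis weights for the 4 support knots, t in [0,1)
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// Evaluate the FFD at arbitrary continuous voxel coordinates (planning grid).
// coef: length 3 * ncx*ncy*ncz (component-major blocks), displacements in mm.
// [[Rcpp::export]]
NumericMatrix cpp_ffd_eval(NumericVector coef, IntegerVector nc,
                           NumericVector ctrl_origin, NumericVector ctrl_spacing,
                           NumericVector cx, NumericVector cy, NumericVector cz) {
  const int ncx = nc[0], ncy = nc[1], ncz = nc[2];
  const R_xlen_t nctrl = (R_xlen_t)ncx * ncy * ncz;
  const R_xlen_t n = cx.size();
  NumericMatrix out(n, 3);
  const double *c0 = coef.begin();
  double wx[4], wy[4], wz[4];
  for (R_xlen_t t = 0; t < n; ++t) {
    double tx = (cx[t] - ctrl_origin[0]) / ctrl_spacing[0];
    double ty = (cy[t] - ctrl_origin[1]) / ctrl_spacing[1];
    double tz = (cz[t] - ctrl_origin[2]) / ctrl_spacing[2];
    int ix = (int)std::floor(tx), iy = (int)std::floor(ty), iz = (int)std::floor(tz);
    // support indices ix-1 .. ix+2 must lie inside the control grid
    if (ix - 1 < 0 || iy - 1 < 0 || iz - 1 < 0 ||
        ix + 2 >= ncx || iy + 2 >= ncy || iz + 2 >= ncz) {
      out(t, 0) = 0.0; out(t, 1) = 0.0; out(t, 2) = 0.0;
      continue;
    }
    bspline_w(tx - ix, wx);
    bspline_w(ty - iy, wy);
    bspline_w(tz - iz, wz);
    double u0 = 0, u1 = 0, u2 = 0;
    for (int c = 0; c < 4; ++c) {
      for (int b = 0; b < 4; ++b) {
        double wyz = wy[b] * wz[c];
        R_xlen_t base = idx3(ix - 1, iy - 1 + b, iz - 1 + c, ncx, ncy);
        for (int a = 0; a < 4; ++a) {
          double w = wx[a] * wyz;
          R_xlen_t ci = base + a;
          u0 += w * c0[ci];
          u1 += w * c0[ci + nctrl];
          u2 += w * c0[ci + 2 * nctrl];
        }
      }
    }
    out(t, 0) = u0; out(t, 1) = u1; out(t, 2) = u2;
  }
  return out;
}

// Trilinear sample with in-cell analytic gradient (per voxel unit).
static inline double sample_grad(const double *a, int nx, int ny, int nz,
                                 double x, double y, double z, double *g) {
  g[0] = g[1] = g[2] = 0.0;
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0)
    return 0.0;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 >= nx - 1) i0 = nx - 2;
  if (j0 >= ny - 1) j0 = ny - 2;
  if (k0 >= nz - 1) k0 = nz - 2;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double c000 = a[idx3(i0, j0, k0, nx, ny)],     c100 = a[idx3(i0 + 1, j0, k0, nx, ny)];
  double c010 = a[idx3(i0, j0 + 1, k0, nx, ny)], c110 = a[idx3(i0 + 1, j0 + 1, k0, nx, ny)];
  double c001 = a[idx3(i0, j0, k0 + 1, nx, ny)], c101 = a[idx3(i0 + 1, j0, k0 + 1, nx, ny)];
  double c011 = a[idx3(i0, j0 + 1, k0 + 1, nx, ny)], c111 = a[idx3(i0 + 1, j0 + 1, k0 + 1, nx, ny)];
  double gx = (1 - fy) * (1 - fz) * (c100 - c000) + fy * (1 - fz) * (c110 - c010) +
              (1 - fy) * fz * (c101 - c001) + fy * fz * (c111 - c011);
  double gy = (1 - fx) * (1 - fz) * (c010 - c000) + fx * (1 - fz) * (c110 - c100) +
              (1 - fx) * fz * (c011 - c001) + fx * fz * (c111 - c101);
  double gz = (1 - fx) * (1 - fy) * (c001 - c000) + fx * (1 - fy) * (c101 - c100) +
              (1 - fx) * fy * (c011 - c010) + fx * fy * (c111 - c110);
  g[0] = gx; g[1] = gy; g[2] = gz;
  double c00 = c000 + fx * (c100 - c000);
  double c10 = c010 + fx * (c110 - c010);
  double c01 = c001 + fx * (c101 - c001);
  double c11 = c011 + fx * (c111 - c011);
  double c0 = c00 + fy * (c10 - c00);
  double c1 = c01 + fy * (c11 - c01);
  return c0 + fz * (c1 - c0);
}

// SSD data cost + bending-energy penalty and full gradient.
// fixedCh: nroi x C matrix of fixed-channel values at the ROI voxels.
// movingCh: list of C full arrays (same grid as fixed).
// roi_*: 0-based integer voxel coordinates of the ROI voxels.
// weights: per-channel weights (already normalized).
// Returns list(cost, grad, data, bend).
// [[Rcpp::export]]
List cpp_ffd_cost_grad(NumericVector coef, IntegerVector nc,
                       NumericVector ctrl_origin, NumericVector ctrl_spacing,
                       IntegerVector roi_i, IntegerVector roi_j, IntegerVector roi_k,
                       NumericMatrix fixedCh, List movingCh,
                       NumericVector weights, IntegerVector dim,
                       NumericVector spacing, double lambda) {
  const int ncx = nc[0], ncy = nc[1], ncz = nc[2];
  const R_xlen_t nctrl = (R_xlen_t)ncx * ncy * ncz;
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nroi = roi_i.size();
  const int C = movingCh.size();
  NumericVector grad(3 * nctrl);
  const double *c0 = coef.begin();
  double *g0 = grad.begin();

  std::vector<const double *> mv(C);
  for (int c = 0; c < C; ++c) {
    NumericVector m = movingCh[c];
    mv[c] = m.begin();
  }

  double data_cost = 0.0;
  double wx[4], wy[4], wz[4], gch[3];

  for (R_xlen_t t = 0; t < nroi; ++t) {
    double px = roi_i[t], py = roi_j[t], pz = roi_k[t];
    double tx = (px - ctrl_origin[0]) / ctrl_spacing[0];
    double ty = (py - ctrl_origin[1]) / ctrl_spacing[1];
    double tz = (pz - ctrl_origin[2]) / ctrl_spacing[2];
    int ix = (int)std::floor(tx), iy = (int)std::floor(ty), iz = (int)std::floor(tz);
    if (ix - 1 < 0 || iy - 1 < 0 || iz - 1 < 0 ||
        ix + 2 >= ncx || iy + 2 >= ncy || iz + 2 >= ncz)
      continue;  // outside FFD support: identity, no gradient
    bspline_w(tx - ix, wx);
    bspline_w(ty - iy, wy);
    bspline_w(tz - iz, wz);
    double u0 = 0, u1 = 0, u2 = 0;
    for (int c = 0; c < 4; ++c)
      for (int b = 0; b < 4; ++b) {
        double wyz = wy[b] * wz[c];
        R_xlen_t base = idx3(ix - 1, iy - 1 + b, iz - 1 + c, ncx, ncy);
        for (int a = 0; a < 4; ++a) {
          double w = wx[a] * wyz;
          u0 += w * c0[base + a];
          u1 += w * c0[base + a + nctrl];
          u2 += w * c0[base + a + 2 * nctrl];
        }
      }
    // warped position in voxel units (u in mm)
    double yx = px + u0 / spacing[0];
    double yy = py + u1 / spacing[1];
    double yz = pz + u2 / spacing[2];

    double rx = 0, ry = 0, rz = 0;  // accumulated residual * dM/dy (mm^-1)
    for (int c = 0; c < C; ++c) {
      double val = sample_grad(mv[c], nx, ny, nz, yx, yy, yz, gch);
      double r = val - fixedCh(t, c);
      double w2 = 2.0 * weights[c];
      data_cost += weights[c] * r * r;
      rx += w2 * r * gch[0] / spacing[0];
      ry += w2 * r * gch[1] / spacing[1];
      rz += w2 * r * gch[2] / spacing[2];
    }
    // scatter into the 64 control points
    for (int c = 0; c < 4; ++c)
      for (int b = 0; b < 4; ++b) {
        double wyz = wy[b] * wz[c];
        R_xlen_t base = idx3(ix - 1, iy - 1 + b, iz - 1 + c, ncx, ncy);
        for (int a = 0; a < 4; ++a) {
          double w = wx[a] * wyz;
          g0[base + a] += w * rx;
          g0[base + a + nctrl] += w * ry;
          g0[base + a + 2 * nctrl] += w * rz;
        }
      }
  }
  double inv_n = nroi > 0 ? 1.0 / (double)nroi : 0.0;
  data_cost *= inv_n;
  for (R_xlen_t t = 0; t < 3 * nctrl; ++t) g0[t] *= inv_n;

  // bending penalty: mean squared second difference of control displacements
  double bend = 0.0;
  if (lambda > 0) {
    double inv_m = 1.0 / (double)(3 * nctrl);
    for (int comp = 0; comp < 3; ++comp) {
      const double *cc = c0 + comp * nctrl;
      double *gg = g0 + comp * nctrl;
      for (int k = 0; k < ncz; ++k)
        for (int j = 0; j < ncy; ++j)
          for (int i = 0; i < ncx; ++i) {
            R_xlen_t id = idx3(i, j, k, ncx, ncy);
            if (i >= 1 && i <= ncx - 2) {
              double d = cc[id - 1] - 2.0 * cc[id] + cc[id + 1];
              bend += d * d * inv_m;
              double s = 2.0 * lambda * d * inv_m;
              gg[id - 1] += s; gg[id] -= 2.0 * s; gg[id + 1] += s;
            }
            if (j >= 1 && j <= ncy - 2) {
              double d = cc[id - ncx] - 2.0 * cc[id] + cc[id + ncx];
              bend += d * d * inv_m;
              double s = 2.0 * lambda * d * inv_m;
              gg[id - ncx] += s; gg[id] -= 2.0 * s; gg[id + ncx] += s;
            }
            R_xlen_t st = (R_xlen_t)ncx * ncy;
            if (k >= 1 && k <= ncz - 2) {
              double d = cc[id - st] - 2.0 * cc[id] + cc[id + st];
              bend += d * d * inv_m;
              double s = 2.0 * lambda * d * inv_m;
              gg[id - st] += s; gg[id] -= 2.0 * s; gg[id + st] += s;
            }
          }
    }
  }
  double cost = data_cost + lambda * bend;
  return List::create(_["cost"] = cost, _["grad"] = grad,
                      _["data"] = data_cost, _["bend"] = bend);
}

// ---------------------------------------------------------------------------
// 3D global gamma index (Wendling-style sorted-offset search with early
// termination). Dose criterion and threshold are absolute (Gy); distances mm.
// Returns gamma for every voxel; the caller applies the evaluation threshold.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_gamma(NumericVector ref, NumericVector ev, IntegerVector dim,
                        NumericVector spacing, double dose_crit,
                        double dta_mm, double radius_mm, double step_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);

  // candidate offsets (mm) on a regular sub-voxel lattice, sorted by distance
  struct Off { double dx, dy, dz, r2; };
  std::vector<Off> offs;
  int mx = (int)std::floor(radius_mm / step_mm);
  offs.reserve((2 * mx + 1) * (2 * mx + 1) * (2 * mx + 1) / 2);
  for (int a = -mx; a <= mx; ++a)
    for (int b = -mx; b <= mx; ++b)
      for (int c = -mx; c <= mx; ++c) {
        double dx = a * step_mm, dy = b * step_mm, dz = c * step_mm;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 <= radius_mm * radius_mm) offs.push_back({dx, dy, dz, r2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Off &p, const Off &q) { return p.r2 < q.r2; });

  const double *e = ev.begin();
  const double dta2 = dta_mm * dta_mm;
  const double dc2 = dose_crit * dose_crit;

  for (R_xlen_t t = 0; t < n; ++t) {
    int i = (int)(t % nx);
    int j = (int)((t / nx) % ny);
    int k = (int)(t / ((R_xlen_t)nx * ny));
    double dref = ref[t];
    double best = std::numeric_limits<double>::infinity();
    for (size_t o = 0; o < offs.size(); ++o) {
      double dist2 = offs[o].r2 / dta2;
      if (dist2 >= best) break;  // offsets sorted: no better candidate exists
      double x = i + offs[o].dx / spacing[0];
      double y = j + offs[o].dy / spacing[1];
      double z = k + offs[o].dz / spacing[2];
      if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
        continue;
      int i0 = std::min((int)std::floor(x), nx - 2);
      int j0 = std::min((int)std::floor(y), ny - 2);
      int k0 = std::min((int)std::floor(z), nz - 2);
      if (i0 < 0) i0 = 0;
      if (j0 < 0) j0 = 0;
      if (k0 < 0) k0 = 0;
      double fx = x - i0, fy = y - j0, fz = z - k0;
      double c00 = e[idx3(i0, j0, k0, nx, ny)] * (1 - fx) + e[idx3(i0 + 1, j0, k0, nx, ny)] * fx;
      double c10 = e[idx3(i0, j0 + 1, k0, nx, ny)] * (1 - fx) + e[idx3(i0 + 1, j0 + 1, k0, nx, ny)] * fx;
      double c01 = e[idx3(i0, j0, k0 + 1, nx, ny)] * (1 - fx) + e[idx3(i0 + 1, j0, k0 + 1, nx, ny)] * fx;
      double c11 = e[idx3(i0, j0 + 1, k0 + 1, nx, ny)] * (1 - fx) + e[idx3(i0 + 1, j0 + 1, k0 + 1, nx, ny)] * fx;
      double c0 = c00 + fy * (c10 - c00);
      double c1 = c01 + fy * (c11 - c01);
      double dev = c0 + fz * (c1 - c0);
      double dd = dev - dref;
      double g2 = dist2 + dd * dd / dc2;
      if (g2 < best) best = g2;
    }
    out[t] = std::sqrt(best);
  }
  return out;
}
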
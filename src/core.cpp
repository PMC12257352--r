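// Low-level numerical kernels: trilinear sampling, pull-back warping,
// displacement-field composition/inversion, Jacobian determinants,
// separable Gaussian smoothing, anisotropic Euclidean distance transforms,
// 3-D gamma analysis and the demons update force.
//
// Geometry convention (shared with the R layer): axis-aligned grids,
// identity orientation, 0-based voxel indices, physical position of voxel
// (i,j,k) = origin + (i,j,k) * spacing, all lengths in mm. Arrays are
// column-major (R layout), linear index i + nx*(j + ny*k); vector fields
// append the component as a 4th dimension.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  double sx, sy, sz;
  double ox, oy, oz;
  Grid(const IntegerVector& dim, const NumericVector& sp, const NumericVector& org)
    : nx(dim[0]), ny(dim[1]), nz(dim[2]),
      sx(sp[0]), sy(sp[1]), sz(sp[2]),
      ox(org[0]), oy(org[1]), oz(org[2]) {}
  R_xlen_t nvox() const { return (R_xlen_t)nx * ny * nz; }
};

inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear interpolation at continuous index (cx,cy,cz).
// If clamp_edge, coordinates are clamped to the lattice (constant
// extrapolation); otherwise out-of-lattice points return `fill` and set *ok
// to false when ok is non-null.
inline double interp3(const double* v, const Grid& g,
                      double cx, double cy, double cz,
                      bool linear, bool clamp_edge, double fill,
                      bool* ok = nullptr) {
  if (ok) *ok = true;
  const double eps = 1e-6;  // tolerate round-off at the lattice boundary
  if (clamp_edge) {
    cx = clampd(cx, 0.0, g.nx - 1.0);
    cy = clampd(cy, 0.0, g.ny - 1.0);
    cz = clampd(cz, 0.0, g.nz - 1.0);
  } else if (cx < -eps || cy < -eps || cz < -eps ||
             cx > g.nx - 1.0 + eps || cy > g.ny - 1.0 + eps || cz > g.nz - 1.0 + eps) {
    if (ok) *ok = false;
    return fill;
  } else {
    cx = clampd(cx, 0.0, g.nx - 1.0);
    cy = clampd(cy, 0.0, g.ny - 1.0);
    cz = clampd(cz, 0.0, g.nz - 1.0);
  }
  if (!linear) {
    int i = (int)std::lround(cx), j = (int)std::lround(cy), k = (int)std::lround(cz);
    return v[i + (R_xlen_t)g.nx * (j + (R_xlen_t)g.ny * k)];
  }
  int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy), k0 = (int)std::floor(cz);
  if (i0 > g.nx - 2) i0 = g.nx - 2;
  if (j0 > g.ny - 2) j0 = g.ny - 2;
  if (k0 > g.nz - 2) k0 = g.nz - 2;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  double fx = cx - i0, fy = cy - j0, fz = cz - k0;
  R_xlen_t sY = g.nx, sZ = (R_xlen_t)g.nx * g.ny;
  const double* p = v + i0 + sY * j0 + sZ * k0;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[sY] * (1 - fx) + p[sY + 1] * fx;
  double c01 = p[sZ] * (1 - fx) + p[sZ + 1] * fx;
  double c11 = p[sZ + sY] * (1 - fx) + p[sZ + sY + 1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

inline void phys_to_cont(const Grid& g, double px, double py, double pz,
                         double& cx, double& cy, double& cz) {
  cx = (px - g.ox) / g.sx;
  cy = (py - g.oy) / g.sy;
  cz = (pz - g.oz) / g.sz;
}

// Sample a displacement field (clamped-edge, trilinear) at a physical point.
inline void sample_disp(const double* d, const Grid& g,
                        double px, double py, double pz,
                        double& ux, double& uy, double& uz) {
  double cx, cy, cz;
  phys_to_cont(g, px, py, pz, cx, cy, cz);
  R_xlen_t n = g.nvox();
  ux = interp3(d,         g, cx, cy, cz, true, true, 0.0);
  uy = interp3(d + n,     g, cx, cy, cz, true, true, 0.0);
  uz = interp3(d + 2 * n, g, cx, cy, cz, true, true, 0.0);
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_sample(NumericVector vals, IntegerVector dim,
                         NumericVector sp, NumericVector org,
                         NumericMatrix pts, bool linear, double fill) {
  Grid g(dim, sp, org);
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double* v = REAL(vals);
  for (R_xlen_t q = 0; q < n; ++q) {
    double cx, cy, cz;
    phys_to_cont(g, pts(q, 0), pts(q, 1), pts(q, 2), cx, cy, cz);
    out[q] = interp3(v, g, cx, cy, cz, linear, false, fill);
  }
  return out;
}

// Pull-back warp/resample: out(x) = moving(x + u(x)) for every voxel x of the
// target grid. An empty displacement vector means u = 0 (pure resampling).
// The displacement field is sampled with clamped-edge trilinear
// interpolation so coarse field grids extend to the target boundary.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector mov, IntegerVector mdim, NumericVector msp, NumericVector morg,
                       NumericVector disp, IntegerVector fdim, NumericVector fsp, NumericVector forg,
                       IntegerVector tdim, NumericVector tsp, NumericVector torg,
                       bool linear, double fill, bool clamp = false) {
  Grid gm(mdim, msp, morg), gt(tdim, tsp, torg);
  bool have_field = disp.size() > 0;
  Grid gf = have_field ? Grid(fdim, fsp, forg) : gm;
  const double* mv = REAL(mov);
  const double* dv = have_field ? REAL(disp) : nullptr;
  NumericVector out((R_xlen_t)gt.nvox());
  double* ov = REAL(out);
  R_xlen_t idx = 0;
  for (int k = 0; k < gt.nz; ++k) {
    double pz = gt.oz + k * gt.sz;
    for (int j = 0; j < gt.ny; ++j) {
      double py = gt.oy + j * gt.sy;
      for (int i = 0; i < gt.nx; ++i, ++idx) {
        double px = gt.ox + i * gt.sx;
        double ux = 0, uy = 0, uz = 0;
        if (have_field) sample_disp(dv, gf, px, py, pz, ux, uy, uz);
        double cx, cy, cz;
        phys_to_cont(gm, px + ux, py + uy, pz + uz, cx, cy, cz);
        ov[idx] = interp3(mv, gm, cx, cy, cz, linear, clamp, fill);
      }
    }
  }
  out.attr("dim") = tdim;
  return out;
}

// Composition on the inner grid: w(x) = u_in(x) + u_out(x + u_in(x)).
// [[Rcpp::export]]
NumericVector cpp_compose(NumericVector dout, IntegerVector odim, NumericVector osp, NumericVector oorg,
                          NumericVector din, IntegerVector idim, NumericVector isp, NumericVector iorg) {
  Grid go(odim, osp, oorg), gi(idim, isp, iorg);
  const double* po = REAL(dout);
  const double* pi = REAL(din);
  R_xlen_t n = gi.nvox();
  NumericVector w(3 * n);
  double* pw = REAL(w);
  R_xlen_t idx = 0;
  for (int k = 0; k < gi.nz; ++k) {
    double pz = gi.oz + k * gi.sz;
    for (int j = 0; j < gi.ny; ++j) {
      double py = gi.oy + j * gi.sy;
      for (int i = 0; i < gi.nx; ++i, ++idx) {
        double px = gi.ox + i * gi.sx;
        double ax = pi[idx], ay = pi[idx + n], az = pi[idx + 2 * n];
        double bx, by, bz;
        sample_disp(po, go, px + ax, py + ay, pz + az, bx, by, bz);
        pw[idx] = ax + bx;
        pw[idx + n] = ay + by;
        pw[idx + 2 * n] = az + bz;
      }
    }
  }
  w.attr("dim") = IntegerVector::create(gi.nx, gi.ny, gi.nz, 3);
  return w;
}

// Fixed-point inversion with damping: v <- v + alpha * (-u(x + v) - v),
// v_0 = -alpha * u. alpha = 1 is the classical iteration; alpha < 1 keeps
// the iteration contractive when the displacement Jacobian has row norms
// above 1 (strong local compression, e.g. organ shrinkage). Returns the
// inverse field, the per-voxel composition residual |u(x + v(x)) + v(x)|
// and iteration diagnostics.
// [[Rcpp::export]]
List cpp_invert(NumericVector disp, IntegerVector dim, NumericVector sp, NumericVector org,
                double tol, int max_iter, double alpha) {
  Grid g(dim, sp, org);
  const double* u = REAL(disp);
  R_xlen_t n = g.nvox();
  NumericVector v(3 * n);
  double* pv = REAL(v);
  for (R_xlen_t q = 0; q < 3 * n; ++q) pv[q] = -alpha * u[q];
  std::vector<double> vnew(3 * n);
  int it = 0;
  double max_update = 0.0;
  for (it = 1; it <= max_iter; ++it) {
    max_update = 0.0;
    R_xlen_t idx = 0;
    for (int k = 0; k < g.nz; ++k) {
      double pz = g.oz + k * g.sz;
      for (int j = 0; j < g.ny; ++j) {
        double py = g.oy + j * g.sy;
        for (int i = 0; i < g.nx; ++i, ++idx) {
          double px = g.ox + i * g.sx;
          double ux, uy, uz;
          sample_disp(u, g, px + pv[idx], py + pv[idx + n], pz + pv[idx + 2 * n], ux, uy, uz);
          double dx = -ux - pv[idx], dy = -uy - pv[idx + n], dz = -uz - pv[idx + 2 * n];
          double upd = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (upd > max_update) max_update = upd;
          vnew[idx] = pv[idx] + alpha * dx;
          vnew[idx + n] = pv[idx + n] + alpha * dy;
          vnew[idx + 2 * n] = pv[idx + 2 * n] + alpha * dz;
        }
      }
    }
    std::copy(vnew.begin(), vnew.end(), pv);
    if (max_update < tol) break;
  }
  NumericVector resid(n);
  double* pr = REAL(resid);
  R_xlen_t idx = 0;
  for (int k = 0; k < g.nz; ++k) {
    double pz = g.oz + k * g.sz;
    for (int j = 0; j < g.ny; ++j) {
      double py = g.oy + j * g.sy;
      for (int i = 0; i < g.nx; ++i, ++idx) {
        double px = g.ox + i * g.sx;
        double ux, uy, uz;
        sample_disp(u, g, px + pv[idx], py + pv[idx + n], pz + pv[idx + 2 * n], ux, uy, uz);
        double rx = ux + pv[idx], ry = uy + pv[idx + n], rz = uz + pv[idx + 2 * n];
        pr[idx] = std::sqrt(rx * rx + ry * ry + rz * rz);
      }
    }
  }
  v.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz, 3);
  resid.attr("dim") = dim;
  return List::create(_["disp"] = v, _["residual"] = resid,
                      _["iterations"] = it > max_iter ? max_iter : it,
                      _["max_update"] = max_update);
}

// Jacobian determinant of T(x) = x + u(x), central differences in the
// interior and one-sided differences at lattice borders.
// [[Rcpp::export]]
NumericVector cpp_jacobian_det(NumericVector disp, IntegerVector dim, NumericVector sp) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double s[3] = { sp[0], sp[1], sp[2] };
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double* u = REAL(disp);
  NumericVector det(n);
  double* pd = REAL(det);
  R_xlen_t sY = nx, sZ = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = i + sY * j + sZ * k;
        double J[3][3];
        int lo[3] = { i > 0 ? -1 : 0, j > 0 ? -1 : 0, k > 0 ? -1 : 0 };
        int hi[3] = { i < nx - 1 ? 1 : 0, j < ny - 1 ? 1 : 0, k < nz - 1 ? 1 : 0 };
        R_xlen_t stride[3] = { 1, sY, sZ };
        for (int c = 0; c < 3; ++c) {        // component
          const double* uc = u + (R_xlen_t)c * n;
          for (int a = 0; a < 3; ++a) {      // derivative axis
            double h = (hi[a] - lo[a]) * s[a];
            double dv = h > 0 ? (uc[idx + hi[a] * stride[a]] - uc[idx + lo[a] * stride[a]]) / h : 0.0;
            J[c][a] = dv + (c == a ? 1.0 : 0.0);
          }
        }
        pd[idx] = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
                - J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
                + J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  det.attr("dim") = dim;
  return det;
}

// Separable Gaussian smoothing, kernel truncated at 3 sigma and renormalized
// at lattice edges (no boundary dimming). sigma in mm, isotropic.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vals, IntegerVector dim, NumericVector sp, double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out = clone(vals);
  if (sigma <= 0) { out.attr("dim") = dim; return out; }
  double* cur = REAL(out);
  std::vector<double> tmp(n);
  int dims[3] = { nx, ny, nz };
  R_xlen_t strides[3] = { 1, nx, (R_xlen_t)nx * ny };
  for (int a = 0; a < 3; ++a) {
    double s = sp[a];
    int rad = (int)std::ceil(3.0 * sigma / s);
    if (rad < 1) continue;
    std::vector<double> ker(2 * rad + 1);
    for (int t = -rad; t <= rad; ++t)
      ker[t + rad] = std::exp(-0.5 * (t * s) * (t * s) / (sigma * sigma));
    int na = dims[a];
    R_xlen_t sa = strides[a];
    // iterate over all lines along axis a
    int nb = dims[(a + 1) % 3], nc = dims[(a + 2) % 3];
    R_xlen_t sb = strides[(a + 1) % 3], sc = strides[(a + 2) % 3];
    for (int c = 0; c < nc; ++c)
      for (int b = 0; b < nb; ++b) {
        R_xlen_t base = b * sb + c * sc;
        for (int i = 0; i < na; ++i) {
          double acc = 0, wsum = 0;
          int t0 = std::max(-rad, -i), t1 = std::min(rad, na - 1 - i);
          for (int t = t0; t <= t1; ++t) {
            double w = ker[t + rad];
            acc += w * cur[base + (R_xlen_t)(i + t) * sa];
            wsum += w;
          }
          tmp[base + (R_xlen_t)i * sa] = acc / wsum;
        }
      }
    std::copy(tmp.begin(), tmp.end(), cur);
  }
  out.attr("dim") = dim;
  return out;
}

namespace {
// Felzenszwalb & Huttenlocher 1-D squared distance transform with sample
// pitch s (anisotropic axes handled by per-axis pitch).
void dt1d(std::vector<double>& f, std::vector<double>& d,
          std::vector<int>& v, std::vector<double>& z, int n, double s) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    while (true) {
      double xv = v[k] * s;
      double sct = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sct <= z[k]) { --k; continue; }
      ++k;
      v[k] = q;
      z[k] = sct;
      z[k + 1] = std::numeric_limits<double>::infinity();
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}
} // namespace

// Euclidean distance (mm) from every voxel center to the nearest foreground
// voxel center (mask != 0). All-background masks return 1e10 everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt(NumericVector mask, IntegerVector dim, NumericVector sp) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double BIG = 1e20;
  std::vector<double> d2(n);
  const double* m = REAL(mask);
  for (R_xlen_t q = 0; q < n; ++q) d2[q] = (m[q] != 0) ? 0.0 : BIG;
  int dims[3] = { nx, ny, nz };
  R_xlen_t strides[3] = { 1, nx, (R_xlen_t)nx * ny };
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  for (int a = 0; a < 3; ++a) {
    int na = dims[a];
    R_xlen_t sa = strides[a];
    int nb = dims[(a + 1) % 3], nc = dims[(a + 2) % 3];
    R_xlen_t sb = strides[(a + 1) % 3], sc = strides[(a + 2) % 3];
    for (int c = 0; c < nc; ++c)
      for (int b = 0; b < nb; ++b) {
        R_xlen_t base = b * sb + c * sc;
        for (int i = 0; i < na; ++i) f[i] = d2[base + (R_xlen_t)i * sa];
        dt1d(f, dd, v, z, na, sp[a]);
        for (int i = 0; i < na; ++i) d2[base + (R_xlen_t)i * sa] = dd[i];
      }
  }
  NumericVector out(n);
  for (R_xlen_t q = 0; q < n; ++q) out[q] = d2[q] >= BIG ? 1e10 : std::sqrt(d2[q]);
  out.attr("dim") = dim;
  return out;
}

namespace {
struct GOffset { double dx, dy, dz, dist2; };

std::vector<GOffset> gamma_offsets(double step, double cap, bool sorted) {
  int m = (int)std::floor(cap / step + 1e-9);
  std::vector<GOffset> offs;
  offs.reserve((2 * m + 1) * (2 * m + 1) * (2 * m + 1) / 2);
  for (int a = -m; a <= m; ++a)
    for (int b = -m; b <= m; ++b)
      for (int c = -m; c <= m; ++c) {
        double dx = a * step, dy = b * step, dz = c * step;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= cap * cap + 1e-9) offs.push_back({ dx, dy, dz, d2 });
      }
  if (sorted)
    std::sort(offs.begin(), offs.end(),
              [](const GOffset& p, const GOffset& q) { return p.dist2 < q.dist2; });
  return offs;
}
} // namespace

// 3-D gamma analysis. Reference voxels with dose >= thr_abs are evaluated;
// candidate points lie on a subvoxel lattice of pitch `step` within radius
// `cap` around the reference voxel and the evaluated dose is sampled there
// by trilinear interpolation (candidates outside the evaluated volume are
// skipped). Offsets are visited in increasing distance with an early exit
// once the pure distance term exceeds the running minimum.
// [[Rcpp::export]]
List cpp_gamma(NumericVector ref, IntegerVector rdim, NumericVector rsp, NumericVector rorg,
               NumericVector ev, IntegerVector edim, NumericVector esp, NumericVector eorg,
               double dd_abs, double dta, double thr_abs, double step, double cap) {
  Grid gr(rdim, rsp, rorg), ge(edim, esp, eorg);
  const double* pr = REAL(ref);
  const double* pe = REAL(ev);
  std::vector<GOffset> offs = gamma_offsets(step, cap, true);
  R_xlen_t n = gr.nvox();
  NumericVector gmap(n, NA_REAL);
  double* pg = REAL(gmap);
  double dta2 = dta * dta, dd2 = dd_abs * dd_abs;
  R_xlen_t n_eval = 0, n_pass = 0;
  R_xlen_t idx = 0;
  for (int k = 0; k < gr.nz; ++k) {
    double pz = gr.oz + k * gr.sz;
    for (int j = 0; j < gr.ny; ++j) {
      double py = gr.oy + j * gr.sy;
      for (int i = 0; i < gr.nx; ++i, ++idx) {
        double dref = pr[idx];
        if (!(dref >= thr_abs)) continue;
        double px = gr.ox + i * gr.sx;
        double best = std::numeric_limits<double>::infinity();
        for (const GOffset& o : offs) {
          double dterm = o.dist2 / dta2;
          if (dterm >= best) break;  // sorted: no later offset can win
          double cx, cy, cz;
          phys_to_cont(ge, px + o.dx, py + o.dy, pz + o.dz, cx, cy, cz);
          bool ok;
          double de = interp3(pe, ge, cx, cy, cz, true, false, 0.0, &ok);
          if (!ok) continue;
          double g2 = dterm + (de - dref) * (de - dref) / dd2;
          if (g2 < best) best = g2;
        }
        double gam = std::isfinite(best) ? std::sqrt(best) : 1e6;
        pg[idx] = gam;
        ++n_eval;
        if (gam <= 1.0) ++n_pass;
      }
    }
  }
  gmap.attr("dim") = rdim;
  return List::create(_["gamma"] = gmap, _["n_evaluated"] = (double)n_eval,
                      _["n_pass"] = (double)n_pass);
}

// Exhaustive-search gamma used as an independent oracle in tests: identical
// candidate-lattice semantics but a plain unsorted full scan with no early
// exit or shortcuts.
// [[Rcpp::export]]
List cpp_gamma_brute(NumericVector ref, IntegerVector rdim, NumericVector rsp, NumericVector rorg,
                     NumericVector ev, IntegerVector edim, NumericVector esp, NumericVector eorg,
                     double dd_abs, double dta, double thr_abs, double step, double cap) {
  Grid gr(rdim, rsp, rorg), ge(edim, esp, eorg);
  const double* pr = REAL(ref);
  const double* pe = REAL(ev);
  std::vector<GOffset> offs = gamma_offsets(step, cap, false);
  R_xlen_t n = gr.nvox();
  NumericVector gmap(n, NA_REAL);
  double* pg = REAL(gmap);
  double dta2 = dta * dta, dd2 = dd_abs * dd_abs;
  R_xlen_t n_eval = 0, n_pass = 0;
  R_xlen_t idx = 0;
  for (int k = 0; k < gr.nz; ++k) {
    double pz = gr.oz + k * gr.sz;
    for (int j = 0; j < gr.ny; ++j) {
      double py = gr.oy + j * gr.sy;
      for (int i = 0; i < gr.nx; ++i, ++idx) {
        double dref = pr[idx];
        if (!(dref >= thr_abs)) continue;
        double px = gr.ox + i * gr.sx;
        double best = std::numeric_limits<double>::infinity();
        for (const GOffset& o : offs) {
          double cx, cy, cz;
          phys_to_cont(ge, px + o.dx, py + o.dy, pz + o.dz, cx, cy, cz);
          bool ok;
          double de = interp3(pe, ge, cx, cy, cz, true, false, 0.0, &ok);
          if (!ok) continue;
          double g2 = o.dist2 / dta2 + (de - dref) * (de - dref) / dd2;
          if (g2 < best) best = g2;
        }
        double gam = std::isfinite(best) ? std::sqrt(best) : 1e6;
        pg[idx] = gam;
        ++n_eval;
        if (gam <= 1.0) ++n_pass;
      }
    }
  }
  gmap.attr("dim") = rdim;
  return List::create(_["gamma"] = gmap, _["n_evaluated"] = (double)n_eval,
                      _["n_pass"] = (double)n_pass);
}

// Demons force for intensity registration: for each voxel,
// du = -(w - f) * grad / (|grad|^2 + (w - f)^2 / K^2) with grad the mean of
// the fixed and warped-moving image gradients and K the mean voxel spacing.
// Updates are capped at max_step mm. Differences below diff_floor (in
// intensity units) give no force: the demons expression is scale-invariant,
// so without a floor even round-off noise drives O(K) updates.
// [[Rcpp::export]]
NumericVector cpp_demons_update(NumericVector fixed, NumericVector warped,
                                IntegerVector dim, NumericVector sp, double max_step,
                                double diff_floor = 0.5) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double* f = REAL(fixed);
  const double* w = REAL(warped);
  NumericVector upd(3 * n);
  double* pu = REAL(upd);
  double K = (sp[0] + sp[1] + sp[2]) / 3.0;
  double K2 = K * K;
  R_xlen_t sY = nx, sZ = (R_xlen_t)nx * ny;
  R_xlen_t stride[3] = { 1, sY, sZ };
  int dims[3] = { nx, ny, nz };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = i + sY * j + sZ * k;
        double diff = w[idx] - f[idx];
        if (std::abs(diff) < diff_floor) continue;
        double g[3];
        int pos[3] = { i, j, k };
        for (int a = 0; a < 3; ++a) {
          int lo = pos[a] > 0 ? -1 : 0;
          int hi = pos[a] < dims[a] - 1 ? 1 : 0;
          double h = (hi - lo) * sp[a];
          double gf = h > 0 ? (f[idx + hi * stride[a]] - f[idx + lo * stride[a]]) / h : 0.0;
          double gw = h > 0 ? (w[idx + hi * stride[a]] - w[idx + lo * stride[a]]) / h : 0.0;
          g[a] = 0.5 * (gf + gw);
        }
        double g2 = g[0] * g[0] + g[1] * g[1] + g[2] * g[2];
        double den = g2 + diff * diff / K2;
        if (den <= 0) continue;
        double scale = -diff / den;
        double ux = scale * g[0], uy = scale * g[1], uz = scale * g[2];
        double mag = std::sqrt(ux * ux + uy * uy + uz * uz);
        if (mag > max_step) {
          double sc = max_step / mag;
          ux *= sc; uy *= sc; uz *= sc;
        }
        pu[idx] = ux; pu[idx + n] = uy; pu[idx + 2 * n] = uz;
      }
  upd.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return upd;
}
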
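// Staggered-grid (MAC) fraction-field projection solver kernels.
//
// Conventions (fixed throughout):
//  - flow is along the third array dimension (z); lateral boundaries are
//    free-slip walls (zero normal velocity, zero tangential gradient);
//  - the inlet face (k = 0) carries a fixed flat velocity profile, the
//    outlet face (k = nz) a reference-pressure (Dirichlet) condition;
//  - face fractions are min(f_left, f_right), so any face touching fully
//    solid material has fraction 0 and its velocity is identically zero;
//  - both the intermediate velocity and the pressure correction are
//    multiplied by the face fraction (the liquid-fraction momentum sink);
//  - where a tangential velocity node lies in fully solid material the
//    diffusion/convection stencil uses a mirror ghost, i.e. no-slip at the
//    intervening face (the bone-fluid interface), which keeps the scheme
//    second-order on wall-aligned channels.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  inline size_t ic(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  }
  inline size_t iu(int i, int j, int k) const {
    return (size_t)i + (size_t)(nx + 1) * ((size_t)j + (size_t)ny * k);
  }
  inline size_t iv(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)(ny + 1) * k);
  }
  inline size_t iw(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  }
  size_t nc() const { return (size_t)nx * ny * nz; }
  size_t nu() const { return (size_t)(nx + 1) * ny * nz; }
  size_t nv() const { return (size_t)nx * (ny + 1) * nz; }
  size_t nw() const { return (size_t)nx * ny * (nz + 1); }
};

// Face fractions with velocity boundary conventions:
//  fu: 0 on lateral x-boundary faces; fv likewise for y;
//  fw: inlet face = f(.,.,0), outlet face = f(.,.,nz-1).
void face_fractions(const Grid& g, const double* f,
                    std::vector<double>& fu, std::vector<double>& fv,
                    std::vector<double>& fw) {
  fu.assign(g.nu(), 0.0);
  fv.assign(g.nv(), 0.0);
  fw.assign(g.nw(), 0.0);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 1; i < g.nx; ++i)
        fu[g.iu(i, j, k)] = std::min(f[g.ic(i - 1, j, k)], f[g.ic(i, j, k)]);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 1; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i)
        fv[g.iv(i, j, k)] = std::min(f[g.ic(i, j - 1, k)], f[g.ic(i, j, k)]);
  for (int k = 1; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i)
        fw[g.iw(i, j, k)] = std::min(f[g.ic(i, j, k - 1)], f[g.ic(i, j, k)]);
  for (int j = 0; j < g.ny; ++j)
    for (int i = 0; i < g.nx; ++i) {
      fw[g.iw(i, j, 0)] = f[g.ic(i, j, 0)];
      fw[g.iw(i, j, g.nz)] = f[g.ic(i, j, g.nz - 1)];
    }
}

// Tangential-neighbour fetch with ghost rules. `val` is the node value at
// the neighbour position if it exists; flags say what lies there.
// kind: 0 = in-domain node, 1 = out-of-domain (free-slip / zero-gradient),
//       2 = out-of-domain mirror (no-slip boundary face),
//       3 = solid node (mirror at intervening cell face).
inline double ghost(double centre, double val, int kind) {
  switch (kind) {
    case 0: return val;
    case 1: return centre;   // zero tangential gradient
    case 2: return -centre;  // no-slip at the boundary face
    default: return -centre; // no-slip at the fluid-solid face
  }
}

inline double upwind(double a, double c, double m, double p, double h) {
  return a > 0 ? a * (c - m) / h : a * (p - c) / h;
}

// One explicit momentum step: ustar = f_face * (u + dt * (-conv + nu_ * lap)).
// Inlet w-face is held at vin * fw and not advanced.
void momentum(const Grid& g, const double* u, const double* v,
              const double* w, const std::vector<double>& fu,
              const std::vector<double>& fv, const std::vector<double>& fw,
              double h, double dt, double nu_, double vin,
              double* us, double* vs, double* ws) {
  const double h2 = h * h;
  // --- u component (x faces), interior i = 1..nx-1 ---
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j) {
      for (int i = 0; i <= g.nx; i += g.nx) us[g.iu(i, j, k)] = 0.0;
      for (int i = 1; i < g.nx; ++i) {
        const size_t id = g.iu(i, j, k);
        const double fface = fu[id];
        if (fface == 0.0) { us[id] = 0.0; continue; }
        const double c = u[id];
        const double xm = u[g.iu(i - 1, j, k)], xp = u[g.iu(i + 1, j, k)];
        int kym = j > 0 ? (fu[g.iu(i, j - 1, k)] == 0.0 ? 3 : 0) : 1;
        int kyp = j < g.ny - 1 ? (fu[g.iu(i, j + 1, k)] == 0.0 ? 3 : 0) : 1;
        int kzm = k > 0 ? (fu[g.iu(i, j, k - 1)] == 0.0 ? 3 : 0) : 2;
        int kzp = k < g.nz - 1 ? (fu[g.iu(i, j, k + 1)] == 0.0 ? 3 : 0) : 1;
        const double ym = ghost(c, j > 0 ? u[g.iu(i, j - 1, k)] : 0.0, kym);
        const double yp = ghost(c, j < g.ny - 1 ? u[g.iu(i, j + 1, k)] : 0.0, kyp);
        const double zm = ghost(c, k > 0 ? u[g.iu(i, j, k - 1)] : 0.0, kzm);
        const double zp = ghost(c, k < g.nz - 1 ? u[g.iu(i, j, k + 1)] : 0.0, kzp);
        const double vbar = 0.25 * (v[g.iv(i - 1, j, k)] + v[g.iv(i - 1, j + 1, k)] +
                                    v[g.iv(i, j, k)] + v[g.iv(i, j + 1, k)]);
        const double wbar = 0.25 * (w[g.iw(i - 1, j, k)] + w[g.iw(i - 1, j, k + 1)] +
                                    w[g.iw(i, j, k)] + w[g.iw(i, j, k + 1)]);
        const double conv = upwind(c, c, xm, xp, h) + upwind(vbar, c, ym, yp, h) +
                            upwind(wbar, c, zm, zp, h);
        // mirror (no-slip interface) neighbours are folded into the
        // diagonal implicitly: unconditionally stable, same steady state
        const double diff_ex = nu_ * ((xm - c) + (xp - c) +
            (kym >= 2 ? 0.0 : ym - c) + (kyp >= 2 ? 0.0 : yp - c) +
            (kzm >= 2 ? 0.0 : zm - c) + (kzp >= 2 ? 0.0 : zp - c)) / h2;
        const int nmirror = (kym >= 2) + (kyp >= 2) + (kzm >= 2) + (kzp >= 2);
        us[id] = fface * (c + dt * (diff_ex - conv)) /
                 (1.0 + dt * nu_ * 2.0 * nmirror / h2);
      }
    }
  // --- v component (y faces), interior j = 1..ny-1 ---
  for (int k = 0; k < g.nz; ++k) {
    for (int i = 0; i < g.nx; ++i) {
      vs[g.iv(i, 0, k)] = 0.0;
      vs[g.iv(i, g.ny, k)] = 0.0;
    }
    for (int j = 1; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        const size_t id = g.iv(i, j, k);
        const double fface = fv[id];
        if (fface == 0.0) { vs[id] = 0.0; continue; }
        const double c = v[id];
        const double ym = v[g.iv(i, j - 1, k)], yp = v[g.iv(i, j + 1, k)];
        int kxm = i > 0 ? (fv[g.iv(i - 1, j, k)] == 0.0 ? 3 : 0) : 1;
        int kxp = i < g.nx - 1 ? (fv[g.iv(i + 1, j, k)] == 0.0 ? 3 : 0) : 1;
        int kzm = k > 0 ? (fv[g.iv(i, j, k - 1)] == 0.0 ? 3 : 0) : 2;
        int kzp = k < g.nz - 1 ? (fv[g.iv(i, j, k + 1)] == 0.0 ? 3 : 0) : 1;
        const double xm = ghost(c, i > 0 ? v[g.iv(i - 1, j, k)] : 0.0, kxm);
        const double xp = ghost(c, i < g.nx - 1 ? v[g.iv(i + 1, j, k)] : 0.0, kxp);
        const double zm = ghost(c, k > 0 ? v[g.iv(i, j, k - 1)] : 0.0, kzm);
        const double zp = ghost(c, k < g.nz - 1 ? v[g.iv(i, j, k + 1)] : 0.0, kzp);
        const double ubar = 0.25 * (u[g.iu(i, j - 1, k)] + u[g.iu(i + 1, j - 1, k)] +
                                    u[g.iu(i, j, k)] + u[g.iu(i + 1, j, k)]);
        const double wbar = 0.25 * (w[g.iw(i, j - 1, k)] + w[g.iw(i, j - 1, k + 1)] +
                                    w[g.iw(i, j, k)] + w[g.iw(i, j, k + 1)]);
        const double conv = upwind(ubar, c, xm, xp, h) + upwind(c, c, ym, yp, h) +
                            upwind(wbar, c, zm, zp, h);
        const double diff_ex = nu_ * ((ym - c) + (yp - c) +
            (kxm >= 2 ? 0.0 : xm - c) + (kxp >= 2 ? 0.0 : xp - c) +
            (kzm >= 2 ? 0.0 : zm - c) + (kzp >= 2 ? 0.0 : zp - c)) / h2;
        const int nmirror = (kxm >= 2) + (kxp >= 2) + (kzm >= 2) + (kzp >= 2);
        vs[id] = fface * (c + dt * (diff_ex - conv)) /
                 (1.0 + dt * nu_ * 2.0 * nmirror / h2);
      }
  }
  // --- w component (z faces): k = 0 fixed inlet, k = 1..nz advanced ---
  for (int j = 0; j < g.ny; ++j)
    for (int i = 0; i < g.nx; ++i)
      ws[g.iw(i, j, 0)] = vin * fw[g.iw(i, j, 0)];
  for (int k = 1; k <= g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        const size_t id = g.iw(i, j, k);
        const double fface = fw[id];
        if (fface == 0.0) { ws[id] = 0.0; continue; }
        const double c = w[id];
        const double zm = w[g.iw(i, j, k - 1)];
        const double zp = k < g.nz ? w[g.iw(i, j, k + 1)] : c; // outflow
        int kxm = i > 0 ? (fw[g.iw(i - 1, j, k)] == 0.0 ? 3 : 0) : 1;
        int kxp = i < g.nx - 1 ? (fw[g.iw(i + 1, j, k)] == 0.0 ? 3 : 0) : 1;
        int kym = j > 0 ? (fw[g.iw(i, j - 1, k)] == 0.0 ? 3 : 0) : 1;
        int kyp = j < g.ny - 1 ? (fw[g.iw(i, j + 1, k)] == 0.0 ? 3 : 0) : 1;
        const double xm = ghost(c, i > 0 ? w[g.iw(i - 1, j, k)] : 0.0, kxm);
        const double xp = ghost(c, i < g.nx - 1 ? w[g.iw(i + 1, j, k)] : 0.0, kxp);
        const double ym = ghost(c, j > 0 ? w[g.iw(i, j - 1, k)] : 0.0, kym);
        const double yp = ghost(c, j < g.ny - 1 ? w[g.iw(i, j + 1, k)] : 0.0, kyp);
        const int kc = std::min(k, g.nz - 1); // cell for face averaging at outlet
        const double ubar = k < g.nz
          ? 0.25 * (u[g.iu(i, j, k - 1)] + u[g.iu(i + 1, j, k - 1)] +
                    u[g.iu(i, j, k)] + u[g.iu(i + 1, j, k)])
          : 0.5 * (u[g.iu(i, j, kc)] + u[g.iu(i + 1, j, kc)]);
        const double vbar = k < g.nz
          ? 0.25 * (v[g.iv(i, j, k - 1)] + v[g.iv(i, j + 1, k - 1)] +
                    v[g.iv(i, j, k)] + v[g.iv(i, j + 1, k)])
          : 0.5 * (v[g.iv(i, j, kc)] + v[g.iv(i, j + 1, kc)]);
        const double conv = upwind(ubar, c, xm, xp, h) + upwind(vbar, c, ym, yp, h) +
                            upwind(c, c, zm, zp, h);
        const double diff_ex = nu_ * ((zm - c) + (zp - c) +
            (kxm >= 2 ? 0.0 : xm - c) + (kxp >= 2 ? 0.0 : xp - c) +
            (kym >= 2 ? 0.0 : ym - c) + (kyp >= 2 ? 0.0 : yp - c)) / h2;
        const int nmirror = (kxm >= 2) + (kxp >= 2) + (kym >= 2) + (kyp >= 2);
        ws[id] = fface * (c + dt * (diff_ex - conv)) /
                 (1.0 + dt * nu_ * 2.0 * nmirror / h2);
      }
}

// Pressure-operator conductances: fu/fv/fw with Neumann closures on the
// inlet (prescribed flux) and lateral boundaries, and a doubled Dirichlet
// conductance on the outlet face (reference pressure at the face itself).
struct PressureOp {
  Grid g;
  const std::vector<double>*cu, *cv, *cw; // velocity face fractions
  std::vector<double> diag;
  std::vector<unsigned char> active;

  void build(const Grid& g_, const std::vector<double>& fu,
             const std::vector<double>& fv, const std::vector<double>& fw,
             const double* f) {
    g = g_;
    cu = &fu; cv = &fv; cw = &fw;
    diag.assign(g.nc(), 0.0);
    for (int k = 0; k < g.nz; ++k)
      for (int j = 0; j < g.ny; ++j)
        for (int i = 0; i < g.nx; ++i) {
          const size_t c = g.ic(i, j, k);
          double d = fu[g.iu(i, j, k)] + fu[g.iu(i + 1, j, k)] +
                     fv[g.iv(i, j, k)] + fv[g.iv(i, j + 1, k)];
          if (k > 0) d += fw[g.iw(i, j, k)];
          if (k < g.nz - 1) d += fw[g.iw(i, j, k + 1)];
          else d += 2.0 * fw[g.iw(i, j, g.nz)]; // outlet Dirichlet face
          diag[c] = d;
        }
    // Active = fluid cells connected to the outlet through positive-
    // fraction faces. Everything else is pinned to p = 0.
    active.assign(g.nc(), 0);
    std::vector<size_t> stack;
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        const size_t c = g.ic(i, j, g.nz - 1);
        if (f[c] > 0.0 && !active[c]) { active[c] = 1; stack.push_back(c); }
      }
    const size_t sx = 1, sy = (size_t)g.nx, sz = (size_t)g.nx * g.ny;
    while (!stack.empty()) {
      size_t c = stack.back(); stack.pop_back();
      int k = (int)(c / sz), j = (int)((c % sz) / sy), i = (int)(c % sy);
      auto push = [&](size_t n) {
        if (!active[n]) { active[n] = 1; stack.push_back(n); }
      };
      if (i > 0 && (*cu)[g.iu(i, j, k)] > 0.0) push(c - sx);
      if (i < g.nx - 1 && (*cu)[g.iu(i + 1, j, k)] > 0.0) push(c + sx);
      if (j > 0 && (*cv)[g.iv(i, j, k)] > 0.0) push(c - sy);
      if (j < g.ny - 1 && (*cv)[g.iv(i, j + 1, k)] > 0.0) push(c + sy);
      if (k > 0 && (*cw)[g.iw(i, j, k)] > 0.0) push(c - sz);
      if (k < g.nz - 1 && (*cw)[g.iw(i, j, k + 1)] > 0.0) push(c + sz);
    }
  }

  bool inlet_connected() const {
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i)
        if (active[g.ic(i, j, 0)]) return true;
    return false;
  }

  // y = A x over active cells (x assumed 0 on inactive cells).
  void apply(const double* x, double* y) const {
    for (int k = 0; k < g.nz; ++k)
      for (int j = 0; j < g.ny; ++j)
        for (int i = 0; i < g.nx; ++i) {
          const size_t c = g.ic(i, j, k);
          if (!active[c]) { y[c] = 0.0; continue; }
          double acc = diag[c] * x[c];
          if (i > 0) acc -= (*cu)[g.iu(i, j, k)] * x[c - 1];
          if (i < g.nx - 1) acc -= (*cu)[g.iu(i + 1, j, k)] * x[c + 1];
          if (j > 0) acc -= (*cv)[g.iv(i, j, k)] * x[c - g.nx];
          if (j < g.ny - 1) acc -= (*cv)[g.iv(i, j + 1, k)] * x[c + g.nx];
          const size_t sz = (size_t)g.nx * g.ny;
          if (k > 0) acc -= (*cw)[g.iw(i, j, k)] * x[c - sz];
          if (k < g.nz - 1) acc -= (*cw)[g.iw(i, j, k + 1)] * x[c + sz];
          y[c] = acc;
        }
  }
};

inline double diagsafe(double d) { return d > 0 ? d : 1.0; }

// Jacobi-preconditioned conjugate gradients. Returns iterations used
// (negative if not converged); relres_out gets ||r|| / ||b||.
int pcg(const PressureOp& A, const std::vector<double>& b,
        std::vector<double>& p, double rtol, int maxit, double* relres_out) {
  const size_t n = b.size();
  std::vector<double> r(n, 0.0), z(n, 0.0), d(n, 0.0), q(n, 0.0);
  A.apply(p.data(), q.data());
  double bnorm2 = 0.0;
  for (size_t c = 0; c < n; ++c) {
    if (!A.active[c]) { r[c] = 0.0; continue; }
    r[c] = b[c] - q[c];
    bnorm2 += b[c] * b[c];
  }
  const double bnorm = std::sqrt(bnorm2);
  const double stop = rtol * (bnorm > 0 ? bnorm : 1.0);
  double rz = 0.0;
  for (size_t c = 0; c < n; ++c)
    if (A.active[c]) {
      z[c] = r[c] / diagsafe(A.diag[c]);
      d[c] = z[c];
      rz += r[c] * z[c];
    }
  double rnorm = 0.0;
  for (size_t c = 0; c < n; ++c) rnorm += r[c] * r[c];
  rnorm = std::sqrt(rnorm);
  int it = 0;
  while (rnorm > stop && it < maxit) {
    A.apply(d.data(), q.data());
    double dq = 0.0;
    for (size_t c = 0; c < n; ++c) if (A.active[c]) dq += d[c] * q[c];
    if (dq <= 0.0) break;
    const double alpha = rz / dq;
    double rz_new = 0.0, rn2 = 0.0;
    for (size_t c = 0; c < n; ++c)
      if (A.active[c]) {
        p[c] += alpha * d[c];
        r[c] -= alpha * q[c];
        z[c] = r[c] / diagsafe(A.diag[c]);
        rz_new += r[c] * z[c];
        rn2 += r[c] * r[c];
      }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (size_t c = 0; c < n; ++c)
      if (A.active[c]) d[c] = z[c] + beta * d[c];
    rnorm = std::sqrt(rn2);
    ++it;
  }
  if (relres_out) *relres_out = bnorm > 0 ? rnorm / bnorm : rnorm;
  return rnorm <= stop ? it : -it;
}

// Divergence of the face-fraction-masked intermediate velocity (the
// quantity the projection step corrects); the inlet face carries the
// prescribed flux unmodified.
void rhs_div(const Grid& g, const double* us, const double* vs,
             const double* ws, const std::vector<double>& fu,
             const std::vector<double>& fv, const std::vector<double>& fw,
             double scale, std::vector<double>& b) {
  b.assign(g.nc(), 0.0);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        const size_t wlo = g.iw(i, j, k), whi = g.iw(i, j, k + 1);
        const double flux_lo = k == 0 ? ws[wlo] : fw[wlo] * ws[wlo];
        b[g.ic(i, j, k)] = scale *
          (fu[g.iu(i + 1, j, k)] * us[g.iu(i + 1, j, k)] -
           fu[g.iu(i, j, k)] * us[g.iu(i, j, k)] +
           fv[g.iv(i, j + 1, k)] * vs[g.iv(i, j + 1, k)] -
           fv[g.iv(i, j, k)] * vs[g.iv(i, j, k)] +
           fw[whi] * ws[whi] - flux_lo);
      }
}

// u = f_face * (us - (dt/rho) grad p): both the intermediate velocity and
// the pressure correction carry the liquid-fraction multiplier, so the
// corrected velocity vanishes identically on solid faces. The inlet face
// keeps its prescribed flux; the outlet face uses the half-cell Dirichlet
// gradient.
void project(const Grid& g, const double* us, const double* vs,
             const double* ws, const double* p,
             const std::vector<double>& fu, const std::vector<double>& fv,
             const std::vector<double>& fw, double h, double dtrho,
             double* u, double* v, double* w) {
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j) {
      u[g.iu(0, j, k)] = 0.0;
      u[g.iu(g.nx, j, k)] = 0.0;
      for (int i = 1; i < g.nx; ++i) {
        const size_t id = g.iu(i, j, k);
        u[id] = fu[id] * (us[id] - dtrho *
          (p[g.ic(i, j, k)] - p[g.ic(i - 1, j, k)]) / h);
      }
    }
  for (int k = 0; k < g.nz; ++k) {
    for (int i = 0; i < g.nx; ++i) {
      v[g.iv(i, 0, k)] = 0.0;
      v[g.iv(i, g.ny, k)] = 0.0;
    }
    for (int j = 1; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        const size_t id = g.iv(i, j, k);
        v[id] = fv[id] * (vs[id] - dtrho *
          (p[g.ic(i, j, k)] - p[g.ic(i, j - 1, k)]) / h);
      }
  }
  for (int j = 0; j < g.ny; ++j)
    for (int i = 0; i < g.nx; ++i) {
      w[g.iw(i, j, 0)] = ws[g.iw(i, j, 0)]; // fixed inlet flux
      for (int k = 1; k < g.nz; ++k) {
        const size_t id = g.iw(i, j, k);
        w[id] = fw[id] * (ws[id] - dtrho *
          (p[g.ic(i, j, k)] - p[g.ic(i, j, k - 1)]) / h);
      }
      const size_t id = g.iw(i, j, g.nz);
      w[id] = fw[id] * (ws[id] - dtrho *
        (0.0 - p[g.ic(i, j, g.nz - 1)]) / (h / 2.0));
    }
}

Grid grid_from(IntegerVector dims) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  return g;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_voxelize(NumericMatrix pts, IntegerVector dims,
                           NumericVector lo, double voxel, double radius) {
  Grid g = grid_from(dims);
  NumericVector f((R_xlen_t)g.nc(), 1.0);
  const double r2 = radius * radius;
  for (int p = 0; p < pts.nrow(); ++p) {
    const double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    const int i0 = std::max(0, (int)std::floor((px - radius - lo[0]) / voxel - 0.5));
    const int i1 = std::min(g.nx - 1, (int)std::ceil((px + radius - lo[0]) / voxel - 0.5));
    const int j0 = std::max(0, (int)std::floor((py - radius - lo[1]) / voxel - 0.5));
    const int j1 = std::min(g.ny - 1, (int)std::ceil((py + radius - lo[1]) / voxel - 0.5));
    const int k0 = std::max(0, (int)std::floor((pz - radius - lo[2]) / voxel - 0.5));
    const int k1 = std::min(g.nz - 1, (int)std::ceil((pz + radius - lo[2]) / voxel - 0.5));
    for (int k = k0; k <= k1; ++k) {
      const double dz = lo[2] + (k + 0.5) * voxel - pz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = lo[1] + (j + 0.5) * voxel - py;
        for (int i = i0; i <= i1; ++i) {
          const double dx = lo[0] + (i + 0.5) * voxel - px;
          if (dx * dx + dy * dy + dz * dz <= r2)
            f[g.ic(i, j, k)] = 0.0;
        }
      }
    }
  }
  return f;
}

// [[Rcpp::export]]
List cpp_momentum(NumericVector u, NumericVector v, NumericVector w,
                  NumericVector f, IntegerVector dims, double h, double dt,
                  double rho, double mu, double vin) {
  Grid g = grid_from(dims);
  std::vector<double> fu, fv, fw;
  face_fractions(g, f.begin(), fu, fv, fw);
  NumericVector us((R_xlen_t)g.nu()), vs((R_xlen_t)g.nv()), ws((R_xlen_t)g.nw());
  momentum(g, u.begin(), v.begin(), w.begin(), fu, fv, fw, h, dt, mu / rho,
           vin, us.begin(), vs.begin(), ws.begin());
  return List::create(_["us"] = us, _["vs"] = vs, _["ws"] = ws);
}

// [[Rcpp::export]]
List cpp_pressure_solve(NumericVector us, NumericVector vs, NumericVector ws,
                        NumericVector f, IntegerVector dims, double h,
                        double dt, double rho, NumericVector p0,
                        double rtol, int maxit) {
  Grid g = grid_from(dims);
  std::vector<double> fu, fv, fw;
  face_fractions(g, f.begin(), fu, fv, fw);
  PressureOp A;
  A.build(g, fu, fv, fw, f.begin());
  std::vector<double> b;
  rhs_div(g, us.begin(), vs.begin(), ws.begin(), fu, fv, fw, -rho * h / dt, b);
  for (size_t c = 0; c < g.nc(); ++c) if (!A.active[c]) b[c] = 0.0;
  std::vector<double> p(p0.begin(), p0.end());
  for (size_t c = 0; c < g.nc(); ++c) if (!A.active[c]) p[c] = 0.0;
  double relres = 0.0;
  int it = pcg(A, b, p, rtol, maxit, &relres);
  return List::create(_["p"] = NumericVector(p.begin(), p.end()),
                      _["iterations"] = std::abs(it),
                      _["converged"] = it >= 0,
                      _["relative_residual"] = relres);
}

// [[Rcpp::export]]
List cpp_project(NumericVector us, NumericVector vs, NumericVector ws,
                 NumericVector p, NumericVector f, IntegerVector dims,
                 double h, double dt, double rho) {
  Grid g = grid_from(dims);
  std::vector<double> fu, fv, fw;
  face_fractions(g, f.begin(), fu, fv, fw);
  NumericVector u((R_xlen_t)g.nu()), v((R_xlen_t)g.nv()), w((R_xlen_t)g.nw());
  project(g, us.begin(), vs.begin(), ws.begin(), p.begin(), fu, fv, fw, h,
          dt / rho, u.begin(), v.begin(), w.begin());
  return List::create(_["u"] = u, _["v"] = v, _["w"] = w);
}

// [[Rcpp::export]]
NumericVector cpp_divergence(NumericVector u, NumericVector v,
                             NumericVector w, IntegerVector dims, double h) {
  Grid g = grid_from(dims);
  NumericVector div((R_xlen_t)g.nc());
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i)
        div[g.ic(i, j, k)] =
          (u[g.iu(i + 1, j, k)] - u[g.iu(i, j, k)] +
           v[g.iv(i, j + 1, k)] - v[g.iv(i, j, k)] +
           w[g.iw(i, j, k + 1)] - w[g.iw(i, j, k)]) / h;
  return div;
}

// [[Rcpp::export]]
List cpp_flow_mask(NumericVector f, IntegerVector dims) {
  Grid g = grid_from(dims);
  std::vector<double> fu, fv, fw;
  face_fractions(g, f.begin(), fu, fv, fw);
  PressureOp A;
  A.build(g, fu, fv, fw, f.begin());
  LogicalVector act((R_xlen_t)g.nc());
  for (size_t c = 0; c < g.nc(); ++c) act[c] = A.active[c] != 0;
  return List::create(_["active"] = act,
                      _["open_path"] = A.inlet_connected());
}

// Full pseudo-time march to steady state. Returns the converged state.
// [[Rcpp::export]]
List cpp_steady_flow(NumericVector f, IntegerVector dims, double h,
                     double rho, double mu, double vin, double tol,
                     int max_steps, double cg_rtol, int cg_maxit,
                     Nullable<List> init = R_NilValue,
                     double dt_safety = 0.9, double fixed_dt = -1.0,
                     double cg_rtol_march = 1e-3) {
  Grid g = grid_from(dims);
  const double nu_ = mu / rho;
  std::vector<double> fu, fv, fw;
  face_fractions(g, f.begin(), fu, fv, fw);
  PressureOp A;
  A.build(g, fu, fv, fw, f.begin());
  if (!A.inlet_connected())
    stop("blocked domain: no open flow path from inlet to outlet");

  std::vector<double> u(g.nu(), 0.0), v(g.nv(), 0.0), w(g.nw(), 0.0),
      p(g.nc(), 0.0);
  if (init.isNotNull()) {
    List in(init);
    NumericVector iu = in["u"], iv = in["v"], iw = in["w"], ip = in["p"];
    std::copy(iu.begin(), iu.end(), u.begin());
    std::copy(iv.begin(), iv.end(), v.begin());
    std::copy(iw.begin(), iw.end(), w.begin());
    std::copy(ip.begin(), ip.end(), p.begin());
  } else {
    for (size_t c = 0; c < g.nw(); ++c) w[c] = vin * fw[c]; // plug start
  }
  // velocities must vanish on solid faces even when warm-started
  for (size_t c = 0; c < g.nu(); ++c) if (fu[c] == 0.0) u[c] = 0.0;
  for (size_t c = 0; c < g.nv(); ++c) if (fv[c] == 0.0) v[c] = 0.0;
  for (size_t c = 0; c < g.nw(); ++c) if (fw[c] == 0.0) w[c] = 0.0;

  std::vector<double> us(g.nu()), vs(g.nv()), ws(g.nw()), b;
  double dt = fixed_dt, rel = NA_REAL, relres = 0.0;
  long cg_total = 0, cg_fail = 0;
  bool converged = false;
  int step = 0;
  for (step = 1; step <= max_steps; ++step) {
    if (fixed_dt <= 0 && (step == 1 || step % 20 == 1)) {
      double um = 0, vm = 0, wm = std::abs(vin);
      for (size_t c = 0; c < g.nu(); ++c) um = std::max(um, std::abs(u[c]));
      for (size_t c = 0; c < g.nv(); ++c) vm = std::max(vm, std::abs(v[c]));
      for (size_t c = 0; c < g.nw(); ++c) wm = std::max(wm, std::abs(w[c]));
      dt = dt_safety / (6.0 * nu_ / (h * h) + 2.0 * (um + vm + wm) / h);
    }
    momentum(g, u.data(), v.data(), w.data(), fu, fv, fw, h, dt, nu_, vin,
             us.data(), vs.data(), ws.data());
    rhs_div(g, us.data(), vs.data(), ws.data(), fu, fv, fw, -rho * h / dt, b);
    for (size_t c = 0; c < g.nc(); ++c) if (!A.active[c]) b[c] = 0.0;
    // loose pressure tolerance during the march (the warm-started fixed
    // point is unaffected to O(dt)); tight solve on the final projection
    int it = pcg(A, b, p, cg_rtol_march, cg_maxit, &relres);
    cg_total += std::abs(it);
    if (it < 0) ++cg_fail;
    // project in place, tracking the change
    double dmax = 0.0, vmax = 0.0;
    {
      std::vector<double>& un = us; // reuse buffers for the new field
      std::vector<double>& vn = vs;
      std::vector<double>& wn = ws;
      project(g, us.data(), vs.data(), ws.data(), p.data(), fu, fv, fw, h,
              dt / rho, un.data(), vn.data(), wn.data());
      for (size_t c = 0; c < g.nu(); ++c) {
        dmax = std::max(dmax, std::abs(un[c] - u[c]));
        vmax = std::max(vmax, std::abs(un[c]));
      }
      for (size_t c = 0; c < g.nv(); ++c) {
        dmax = std::max(dmax, std::abs(vn[c] - v[c]));
        vmax = std::max(vmax, std::abs(vn[c]));
      }
      for (size_t c = 0; c < g.nw(); ++c) {
        dmax = std::max(dmax, std::abs(wn[c] - w[c]));
        vmax = std::max(vmax, std::abs(wn[c]));
      }
      u.swap(un); v.swap(vn); w.swap(wn);
    }
    rel = dmax / std::max(vmax, 1e-300);
    if (step % 200 == 0) Rcpp::checkUserInterrupt();
    if (rel < tol) { converged = true; break; }
  }
  // final tight projection so the returned field is divergence-free to
  // the full pressure tolerance
  {
    momentum(g, u.data(), v.data(), w.data(), fu, fv, fw, h, dt, nu_, vin,
             us.data(), vs.data(), ws.data());
    rhs_div(g, us.data(), vs.data(), ws.data(), fu, fv, fw, -rho * h / dt, b);
    for (size_t c = 0; c < g.nc(); ++c) if (!A.active[c]) b[c] = 0.0;
    int it = pcg(A, b, p, cg_rtol, cg_maxit, &relres);
    cg_total += std::abs(it);
    if (it < 0) ++cg_fail;
    project(g, us.data(), vs.data(), ws.data(), p.data(), fu, fv, fw, h,
            dt / rho, u.data(), v.data(), w.data());
  }
  return List::create(
      _["u"] = NumericVector(u.begin(), u.end()),
      _["v"] = NumericVector(v.begin(), v.end()),
      _["w"] = NumericVector(w.begin(), w.end()),
      _["p"] = NumericVector(p.begin(), p.end()),
      _["steps"] = std::min(step, max_steps),
      _["rel_change"] = rel,
      _["converged"] = converged,
      _["dt"] = dt,
      _["cg_iterations"] = (double)cg_total,
      _["cg_failures"] = (double)cg_fail,
      _["cg_relative_residual"] = relres);
}

// Shear-stress tensor components and magnitude at cell centres.
// tau_x = mu (du/dy + dv/dx), tau_y = mu (dv/dz + dw/dy),
// tau_z = mu (dw/dx + du/dz); |tau| = sqrt(tx^2 + ty^2 + tz^2).
// Gradients use central differences of centre-interpolated velocities,
// one-sided half-cell differences toward fully solid neighbours (no-slip
// at the intervening face) and one-sided differences at domain boundaries.
// [[Rcpp::export]]
List cpp_shear(NumericVector u, NumericVector v, NumericVector w,
               NumericVector f, IntegerVector dims, double h, double mu) {
  Grid g = grid_from(dims);
  const size_t n = g.nc();
  std::vector<double> uc(n), vc(n), wc(n);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        const size_t c = g.ic(i, j, k);
        uc[c] = 0.5 * (u[g.iu(i, j, k)] + u[g.iu(i + 1, j, k)]);
        vc[c] = 0.5 * (v[g.iv(i, j, k)] + v[g.iv(i, j + 1, k)]);
        wc[c] = 0.5 * (w[g.iw(i, j, k)] + w[g.iw(i, j, k + 1)]);
      }
  NumericVector tx((R_xlen_t)n), ty((R_xlen_t)n), tz((R_xlen_t)n),
      tau((R_xlen_t)n);
  auto grad = [&](const std::vector<double>& val, int i, int j, int k,
                  int axis) -> double {
    int im = i, jm = j, km = k, ip = i, jp = j, kp = k;
    if (axis == 0) { im--; ip++; }
    else if (axis == 1) { jm--; jp++; }
    else { km--; kp++; }
    const size_t c = g.ic(i, j, k);
    const bool m_in = im >= 0 && jm >= 0 && km >= 0;
    const bool p_in = ip < g.nx && jp < g.ny && kp < g.nz;
    const bool m_solid = m_in && f[g.ic(im, jm, km)] == 0.0;
    const bool p_solid = p_in && f[g.ic(ip, jp, kp)] == 0.0;
    const double vm = m_in ? val[g.ic(im, jm, km)] : 0.0;
    const double vp = p_in ? val[g.ic(ip, jp, kp)] : 0.0;
    if (m_in && p_in && !m_solid && !p_solid) return (vp - vm) / (2.0 * h);
    if (m_solid && p_solid) return 0.0;
    if (m_solid) return (val[c] - 0.0) / (0.5 * h);
    if (p_solid) return (0.0 - val[c]) / (0.5 * h);
    // a domain boundary on one side: one-sided difference inward
    if (!m_in && p_in) return (vp - val[c]) / h;
    if (m_in && !p_in) return (val[c] - vm) / h;
    return 0.0;
  };
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        const size_t c = g.ic(i, j, k);
        if (f[c] == 0.0) { tx[c] = ty[c] = tz[c] = tau[c] = 0.0; continue; }
        const double txv = mu * (grad(uc, i, j, k, 1) + grad(vc, i, j, k, 0));
        const double tyv = mu * (grad(vc, i, j, k, 2) + grad(wc, i, j, k, 1));
        const double tzv = mu * (grad(wc, i, j, k, 0) + grad(uc, i, j, k, 2));
        tx[c] = txv; ty[c] = tyv; tz[c] = tzv;
        tau[c] = std::sqrt(txv * txv + tyv * tyv + tzv * tzv);
      }
  return List::create(_["tx"] = tx, _["ty"] = ty, _["tz"] = tz,
                      _["tau"] = tau);
}
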
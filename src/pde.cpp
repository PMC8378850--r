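// Implicit finite-difference kernels for the coupled density/oxygen system.
//
// Density update: time-backward, space-centered diffusion with upwind
// advection (donor node chosen by the sign of C_i - C_{i-1}), implicit
// reaction term; oxygen update: time-backward diffusion with consumption
// evaluated at the freshly updated density. Both solved as tridiagonal
// systems by the Thomas algorithm. Geometry: planar or radial (radial grid
// is cell-centered, R_i = origin + (i + 1/2) dx, so the no-flux condition
// at r = 0 is built into the inner flux factor).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Thomas algorithm; a = sub, b = diag, c = super, d = rhs (overwritten).
// Returns false on a (near-)singular pivot.
static bool thomas(std::vector<double>& a, std::vector<double>& b,
                   std::vector<double>& c, std::vector<double>& d,
                   std::vector<double>& x) {
  const int n = (int)b.size();
  for (int i = 1; i < n; ++i) {
    if (std::fabs(b[i - 1]) < 1e-300) return false;
    double m = a[i] / b[i - 1];
    b[i] -= m * c[i - 1];
    d[i] -= m * d[i - 1];
  }
  if (std::fabs(b[n - 1]) < 1e-300) return false;
  x[n - 1] = d[n - 1] / b[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = (d[i] - c[i] * x[i + 1]) / b[i];
  return true;
}

struct PdeParams {
  double D, Doxy, r0, b0, C0, C0p, a0, Cb, lam_max;
  int model;    // 0 mean_field, 1 go_or_grow, 2 two_threshold
  int geometry; // 0 planar, 1 radial
  int consumption_constant; // 1: b = b0 always, oxygen unconstrained
  double dx, dt, origin;
};

static PdeParams unpack(const List& par) {
  PdeParams p;
  p.D = par["D"]; p.Doxy = par["Doxy"]; p.r0 = par["r0"]; p.b0 = par["b0"];
  p.C0 = par["C0"]; p.C0p = par["C0p"]; p.a0 = par["a0"];
  p.Cb = par["Cboundary"]; p.lam_max = par["lambda_mf_max"];
  p.model = par["model"]; p.geometry = par["geometry"];
  p.dx = par["dx"]; p.dt = par["dt"]; p.origin = par["origin"];
  p.consumption_constant = par["consumption_constant"];
  return p;
}

// advection magnitude at node i (>= 0); direction comes from sign(C_i - C_{i-1})
static inline double adv_mag(const std::vector<double>& C, int i,
                             const PdeParams& p) {
  if (i == 0) return 0.0;
  double g = (C[i] - C[i - 1]) / p.dx;
  if (p.model == 0) {
    double lam = p.lam_max / (1.0 + std::exp((C[i] - 0.7) / 0.2));
    return std::fabs(lam * g);
  }
  bool go = (p.model == 1) ? (C[i] < p.C0)
                           : (C[i] < p.C0 && C[i] > p.C0p);
  return go ? p.a0 : 0.0;
}

static inline double growth(double C, const PdeParams& p) {
  return (C > p.C0) ? p.r0 : 0.0;
}

static inline double consump(double C, const PdeParams& p) {
  if (p.consumption_constant) return p.b0;
  double v = p.b0 * C / p.C0p;
  return v < p.b0 ? (v > 0.0 ? v : 0.0) : p.b0;
}

struct Workspace {
  std::vector<double> a, b, c, d, x, m, dir;
  explicit Workspace(int n) : a(n), b(n), c(n), d(n), x(n), m(n), dir(n) {}
};

// One full step: implicit rho update, then implicit C update with the new rho.
static bool step_once(std::vector<double>& rho, std::vector<double>& C,
                      const PdeParams& p, Workspace& w) {
  const int n = (int)rho.size();
  std::vector<double>&a = w.a, &b = w.b, &c = w.c, &d = w.d, &x = w.x,
      &m = w.m, &dir = w.dir;
  const double dt = p.dt, dx = p.dx, dx2 = dx * dx;

  for (int i = 0; i < n; ++i) {
    m[i] = adv_mag(C, i, p);
    dir[i] = (i == 0) ? 0.0 : (C[i] > C[i - 1] ? 1.0 : (C[i] < C[i - 1] ? -1.0 : 0.0));
    if (dir[i] == 0.0) m[i] = 0.0; // tie-break: advection vanishes
  }

  // density system
  for (int i = 0; i < n; ++i) {
    double Ri = p.origin + (i + 0.5) * dx;
    double wplus, wminus; // diffusion face weights
    if (p.geometry == 1) {
      wplus = (i == n - 1) ? 0.0 : (Ri + 0.5 * dx) / Ri;
      wminus = (i == 0) ? 0.0 : (Ri - 0.5 * dx) / Ri;
    } else {
      wplus = (i == n - 1) ? 0.0 : 1.0;  // no-flux ends
      wminus = (i == 0) ? 0.0 : 1.0;
    }
    double diag = 1.0 / dt + p.D * (wplus + wminus) / dx2 - growth(C[i], p);
    double sub = (i > 0) ? -p.D * wminus / dx2 : 0.0;
    double sup = (i < n - 1) ? -p.D * wplus / dx2 : 0.0;
    // upwind advection, as printed: donor = node i plus its upstream neighbor
    if (dir[i] > 0.0) { // C increasing: rightward drift, donor left
      diag += m[i] / dx;
      if (i > 0) {
        double fac = (p.geometry == 1)
          ? (p.origin + (i - 0.5) * dx) / Ri : 1.0;
        sub -= fac * m[i - 1] * (dir[i - 1] > 0.0 ? 1.0 : 0.0) / dx;
      }
    } else if (dir[i] < 0.0) { // C decreasing: leftward drift, donor right
      diag += m[i] / dx;
      if (i < n - 1) {
        double fac = (p.geometry == 1)
          ? (p.origin + (i + 1.5) * dx) / Ri : 1.0;
        sup -= fac * m[i + 1] * (dir[i + 1] < 0.0 ? 1.0 : 0.0) / dx;
      }
    }
    a[i] = sub; b[i] = diag; c[i] = sup; d[i] = rho[i] / dt;
  }
  if (!thomas(a, b, c, d, x)) return false;
  rho = x;

  // oxygen system: Dirichlet C = Cb at the outer end, no-flux at the inner end
  for (int i = 0; i < n; ++i) {
    if (i == n - 1) {
      a[i] = 0.0; b[i] = 1.0; c[i] = 0.0; d[i] = p.Cb;
      continue;
    }
    double Ri = p.origin + (i + 0.5) * dx;
    double wplus = 1.0, wminus = (i == 0) ? 0.0 : 1.0;
    if (p.geometry == 1) {
      wplus = (Ri + 0.5 * dx) / Ri;
      wminus = (i == 0) ? 0.0 : (Ri - 0.5 * dx) / Ri;
    }
    b[i] = 1.0 / p.dt + p.Doxy * (wplus + wminus) / dx2;
    a[i] = (i > 0) ? -p.Doxy * wminus / dx2 : 0.0;
    c[i] = -p.Doxy * wplus / dx2;
    d[i] = C[i] / p.dt - consump(C[i], p) * rho[i];
  }
  if (!thomas(a, b, c, d, x)) return false;
  C = x;
  return true;
}

static double front_position(const std::vector<double>& C,
                             const PdeParams& p) {
  // outermost upward crossing of C = C0 (C rises toward the boundary)
  const int n = (int)C.size();
  for (int i = n - 2; i >= 0; --i) {
    if (C[i] < p.C0 && C[i + 1] >= p.C0) {
      double f = (p.C0 - C[i]) / (C[i + 1] - C[i]);
      return p.origin + (i + 0.5 + f) * p.dx;
    }
  }
  return NA_REAL;
}

// [[Rcpp::export(name = ".pde_simulate_cpp")]]
List pde_simulate_cpp(NumericVector rho0, NumericVector C0field, List par,
                      int nsteps, int snap_stride, int front_stride) {
  PdeParams p = unpack(par);
  std::vector<double> rho(rho0.begin(), rho0.end());
  std::vector<double> C(C0field.begin(), C0field.end());
  const int n = (int)rho.size();

  int nsnap = nsteps / snap_stride + 1;
  NumericMatrix rho_snap(nsnap, n), C_snap(nsnap, n);
  NumericVector snap_times(nsnap);
  int nfront = nsteps / front_stride + 1;
  NumericVector front_t(nfront), front_x(nfront);

  Workspace w((int)rho.size());
  int isnap = 0, ifront = 0;
  rho_snap(0, _) = rho0; C_snap(0, _) = C0field; snap_times[0] = 0.0;
  ++isnap;
  front_t[0] = 0.0; front_x[0] = front_position(C, p); ++ifront;

  for (int s = 1; s <= nsteps; ++s) {
    if (!step_once(rho, C, p, w)) {
      stop("singular tridiagonal system at step %d", s);
    }
    if (s % 2000 == 0) {
      double mn = *std::min_element(rho.begin(), rho.end());
      bool bad = !std::isfinite(mn) || mn < -1e-6 * (1.0 + std::fabs(mn));
      for (int i = 0; i < n && !bad; ++i)
        if (!std::isfinite(rho[i]) || !std::isfinite(C[i])) bad = true;
      if (bad) stop("density became NaN or negative beyond tolerance at step %d", s);
    }
    if (s % front_stride == 0 && ifront < nfront) {
      front_t[ifront] = s * p.dt;
      front_x[ifront] = front_position(C, p);
      ++ifront;
    }
    if (s % snap_stride == 0 && isnap < nsnap) {
      for (int i = 0; i < n; ++i) { rho_snap(isnap, i) = rho[i]; C_snap(isnap, i) = C[i]; }
      snap_times[isnap] = s * p.dt;
      ++isnap;
    }
  }
  return List::create(_["times"] = snap_times, _["rho"] = rho_snap,
                      _["C"] = C_snap, _["front_t"] = front_t,
                      _["front_x"] = front_x,
                      _["rho_final"] = NumericVector(rho.begin(), rho.end()),
                      _["C_final"] = NumericVector(C.begin(), C.end()));
}

// Single step, exposed for unit tests.
// [[Rcpp::export(name = ".pde_step_cpp")]]
List pde_step_cpp(NumericVector rho0, NumericVector C0field, List par) {
  PdeParams p = unpack(par);
  std::vector<double> rho(rho0.begin(), rho0.end());
  std::vector<double> C(C0field.begin(), C0field.end());
  Workspace w((int)rho.size());
  if (!step_once(rho, C, p, w)) stop("singular tridiagonal system");
  return List::create(_["rho"] = NumericVector(rho.begin(), rho.end()),
                      _["C"] = NumericVector(C.begin(), C.end()));
}

// Quasi-static oxygen profile for a frozen density: repeated implicit
// relaxation of the C equation with a large pseudo time step.
// [[Rcpp::export(name = ".oxygen_relax_cpp")]]
NumericVector oxygen_relax_cpp(NumericVector rho0, NumericVector Cinit,
                               List par, int iters, double pseudo_dt) {
  PdeParams p = unpack(par);
  p.dt = pseudo_dt;
  const int n = rho0.size();
  std::vector<double> C(Cinit.begin(), Cinit.end());
  std::vector<double> a(n), b(n), c(n), d(n), x(n);
  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < n; ++i) {
      if (i == n - 1) { a[i] = 0; b[i] = 1; c[i] = 0; d[i] = p.Cb; continue; }
      double Ri = p.origin + (i + 0.5) * p.dx;
      double wplus = 1.0, wminus = (i == 0) ? 0.0 : 1.0;
      if (p.geometry == 1) {
        wplus = (Ri + 0.5 * p.dx) / Ri;
        wminus = (i == 0) ? 0.0 : (Ri - 0.5 * p.dx) / Ri;
      }
      double dx2 = p.dx * p.dx;
      // linearized consumption keeps C positive during relaxation
      double q = (C[i] > p.C0p) ? p.b0 * rho0[i] / std::max(C[i], 1e-12)
                                : p.b0 * rho0[i] / p.C0p;
      b[i] = 1.0 / p.dt + p.Doxy * (wplus + wminus) / dx2 + q;
      a[i] = (i > 0) ? -p.Doxy * wminus / dx2 : 0.0;
      c[i] = -p.Doxy * wplus / dx2;
      d[i] = C[i] / p.dt;
    }
    if (!thomas(a, b, c, d, x)) stop("singular system in oxygen relaxation");
    C = x;
  }
  return NumericVector(C.begin(), C.end());
}
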
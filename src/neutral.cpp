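// Implicit stepper for neutral label fractions in the moving frame:
//   dv/dt = D v'' - d/dz((a(z) - sigma) v) + r(z) v
// Coefficients are frozen in time, so the tridiagonal matrix is factored
// once (Thomas forward sweep) and reused every step. Advection uses
// conservative finite-volume upwind fluxes with outflow at the rear end
// and no-flux far ahead.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".neutral_evolve_cpp")]]
List neutral_evolve_cpp(NumericMatrix v0, NumericVector a_z,
                        NumericVector r_z, double sigma, double D,
                        double dz, double dt, int nsteps,
                        IntegerVector window_idx, int record_stride,
                        int absorb_front) {
  const int n = v0.nrow();
  const int K = v0.ncol();
  std::vector<double> w(n); // frame velocity
  for (int i = 0; i < n; ++i) w[i] = a_z[i] - sigma;

  // implicit matrix: (I/dt - L) v_new = v_old/dt
  std::vector<double> sub(n, 0.0), diag(n, 0.0), sup(n, 0.0);
  const double dif = D / (dz * dz);
  for (int i = 0; i < n; ++i) {
    double wm = (i > 0) ? 0.5 * (w[i - 1] + w[i]) : w[0];
    double wp = (i < n - 1) ? 0.5 * (w[i] + w[i + 1]) : 0.0;
    diag[i] = 1.0 / dt - r_z[i];
    if (i > 0) { diag[i] += dif; sub[i] -= dif; }
    if (i < n - 1) { diag[i] += dif; sup[i] -= dif; }
    // flux at i+1/2 (zero at the far-ahead boundary)
    if (i < n - 1) {
      if (wp > 0) diag[i] += wp / dz; else sup[i] += wp / dz;
    }
    // flux at i-1/2 (outflow through the rear end: donor = node 0)
    if (i > 0) {
      if (wm > 0) sub[i] -= wm / dz; else diag[i] -= wm / dz;
    } else if (w[0] < 0) {
      diag[i] -= w[0] / dz; // mass leaves through the rear
    }
  }
  if (absorb_front) { // Dirichlet v = 0 at the far-ahead node
    sub[n - 1] = 0.0; diag[n - 1] = 1.0; sup[n - 1] = 0.0;
  }
  // Thomas prefactorization
  std::vector<double> bb(diag), mm(n, 0.0);
  for (int i = 1; i < n; ++i) {
    mm[i] = sub[i] / bb[i - 1];
    bb[i] -= mm[i] * sup[i - 1];
    if (std::fabs(bb[i]) < 1e-300) stop("singular system in neutral evolve");
  }

  NumericMatrix v(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) v(i, k) = v0(i, k);

  const int nw = window_idx.size();
  int nrec = nsteps / record_stride + 1;
  NumericMatrix shares(nrec, K);
  NumericVector rec_t(nrec);
  int irec = 0;

  std::vector<double> d(n), x(n);
  auto record = [&](int stepno) {
    double tot = 0.0;
    std::vector<double> lab(K, 0.0);
    for (int q = 0; q < nw; ++q) {
      int i = window_idx[q] - 1;
      double s = 0.0;
      for (int k = 0; k < K; ++k) { s += v(i, k); lab[k] += v(i, k); }
      tot += s;
    }
    for (int k = 0; k < K; ++k)
      shares(irec, k) = (tot > 0) ? lab[k] / tot : NA_REAL;
    rec_t[irec] = stepno * dt;
    ++irec;
  };
  record(0);

  for (int s = 1; s <= nsteps; ++s) {
    for (int k = 0; k < K; ++k) {
      for (int i = 0; i < n; ++i) d[i] = v(i, k) / dt;
      if (absorb_front) d[n - 1] = 0.0;
      for (int i = 1; i < n; ++i) d[i] -= mm[i] * d[i - 1];
      x[n - 1] = d[n - 1] / bb[n - 1];
      for (int i = n - 2; i >= 0; --i)
        x[i] = (d[i] - sup[i] * x[i + 1]) / bb[i];
      for (int i = 0; i < n; ++i) v(i, k) = x[i];
    }
    if (s % record_stride == 0 && irec < nrec) record(s);
  }
  return List::create(_["v"] = v, _["share_times"] = rec_t,
                      _["shares"] = shares);
}
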
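// 2-D cellular Potts kernel with oxygen-coupled aerotaxis (chemotaxis up
// the O2 gradient, sigmoid-modulated), aerokinesis (oxygen-dependent
// effective temperature), capped per-pixel consumption, plate-bottom leak,
// Dirichlet borders, and rare stochastic division gated by local oxygen.
// One Monte Carlo step = N*M elementary copy attempts (random target pixel,
// random neighbor source, Metropolis acceptance at the acting cell's
// temperature). All randomness draws from R's RNG so set.seed() makes runs
// bit-reproducible.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct PottsPar {
  double lambda_v, V_target;
  double aero_max, aero_mid, aero_width;
  int aero_flat;
  double T_base, T_amp, T_mid, T_width;
  double consumption, leak, division_prob, division_cutoff;
  int moore, oxygen_dynamic, division_on;
  double Dox_px;
};

static PottsPar unpack(const List& par) {
  PottsPar p;
  p.lambda_v = par["lambda_v"]; p.V_target = par["V_target"];
  p.aero_max = par["lambda_aero_max"]; p.aero_mid = par["aero_midpoint"];
  p.aero_width = par["aero_width"]; p.aero_flat = par["aero_flat"];
  p.T_base = par["T_base"]; p.T_amp = par["T_amp"];
  p.T_mid = par["T_midpoint"]; p.T_width = par["T_width"];
  p.consumption = par["consumption_per_pixel"]; p.leak = par["leak_coeff"];
  p.division_prob = par["division_prob"];
  p.division_cutoff = par["division_cutoff"];
  p.moore = par["moore"]; p.oxygen_dynamic = par["oxygen_dynamic"];
  p.division_on = par["division_on"]; p.Dox_px = par["Dox_px"];
  return p;
}

static inline double lambda_aero(double C, const PottsPar& p) {
  if (p.aero_flat) return p.aero_max;
  return p.aero_max / (1.0 + std::exp((C - p.aero_mid) / p.aero_width));
}

static inline double temperature(double C, const PottsPar& p) {
  if (p.T_amp == 0.0) return p.T_base;
  return p.T_base + p.T_amp / (1.0 + std::exp((C - p.T_mid) / p.T_width));
}

static inline int ri(int n) { // uniform integer in [0, n)
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// [[Rcpp::export(name = ".potts_advance_cpp")]]
List potts_advance_cpp(IntegerMatrix grid_in, NumericMatrix o2_in,
                       IntegerVector vol_in, NumericVector sumx_in,
                       NumericVector sumy_in, IntegerVector lin_in,
                       List par, int nsteps, int do_mc) {
  PottsPar p = unpack(par);
  const int N = grid_in.nrow(), M = grid_in.ncol();
  const int NM = N * M;
  std::vector<int> grid(grid_in.begin(), grid_in.end()); // column-major
  std::vector<double> o2(o2_in.begin(), o2_in.end());
  std::vector<double> buf(o2);
  std::vector<int> vol(vol_in.begin(), vol_in.end());
  std::vector<double> sumx(sumx_in.begin(), sumx_in.end());
  std::vector<double> sumy(sumy_in.begin(), sumy_in.end());
  std::vector<int> lin(lin_in.begin(), lin_in.end());

  const int nn = p.moore ? 8 : 4;
  // neighbor offsets in flat column-major index: (dy, dx) -> dy + dx*N
  int off[8]; int dy8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dx8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  for (int k = 0; k < 8; ++k) off[k] = dy8[k] + dx8[k] * N;

  int* g = grid.data();
  double* C = o2.data();

  auto com_C = [&](int id) -> double {
    int y = (int)std::lround(sumy[id - 1] / vol[id - 1]);
    int x = (int)std::lround(sumx[id - 1] / vol[id - 1]);
    if (y < 0) y = 0; if (y >= N) y = N - 1;
    if (x < 0) x = 0; if (x >= M) x = M - 1;
    return C[y + x * N];
  };

  for (int step = 0; step < nsteps; ++step) {
    if (do_mc) {
      for (int att = 0; att < NM; ++att) {
        int t = ri(NM);
        int ty = t % N, tx = t / N;
        int d = ri(nn);
        int sy = ty + dy8[d], sx = tx + dx8[d];
        if (sy < 0 || sy >= N || sx < 0 || sx >= M) continue;
        int s = t + off[d];
        int id_t = g[t], id_s = g[s];
        if (id_t == id_s) continue;
        if (id_t > 0 && vol[id_t - 1] <= 1) continue; // no cell death
        double dH = 0.0;
        if (id_s > 0) {
          double v = vol[id_s - 1] - p.V_target;
          dH += p.lambda_v * (2.0 * v + 1.0);
        }
        if (id_t > 0) {
          double v = vol[id_t - 1] - p.V_target;
          dH += p.lambda_v * (-2.0 * v + 1.0);
        }
        // chemotaxis: -lambda * (C_target - C_source) for the copy
        // direction, whether the acting cell is extending (cell source)
        // or retreating (medium source); both favor net up-gradient motion
        int acting = (id_s > 0) ? id_s : id_t;
        double Ccell = com_C(acting);
        dH += -lambda_aero(Ccell, p) * (C[t] - C[s]);
        if (dH > 0.0) {
          double T = temperature(Ccell, p);
          if (unif_rand() >= std::exp(-dH / T)) continue;
        }
        // apply the copy
        if (id_t > 0) {
          vol[id_t - 1] -= 1;
          sumx[id_t - 1] -= tx; sumy[id_t - 1] -= ty;
        }
        g[t] = id_s;
        if (id_s > 0) {
          vol[id_s - 1] += 1;
          sumx[id_s - 1] += tx; sumy[id_s - 1] += ty;
        }
      }
    }

    if (p.oxygen_dynamic) {
      // explicit diffusion, sub-stepped to keep D <= 1/4 per sub-step
      int nsub = (int)std::ceil(p.Dox_px / 0.25);
      double Dsub = p.Dox_px / nsub;
      double* a = o2.data();
      double* b = buf.data();
      for (int it = 0; it < nsub; ++it) {
        for (int x = 0; x < M; ++x) {
          double* col = a + x * N;
          double* out = b + x * N;
          if (x == 0 || x == M - 1) {
            for (int y = 0; y < N; ++y) out[y] = 21.0;
            continue;
          }
          out[0] = 21.0; out[N - 1] = 21.0;
          const double* cl = col - N;
          const double* cr = col + N;
          for (int y = 1; y < N - 1; ++y) {
            double lap = col[y - 1] + col[y + 1] + cl[y] + cr[y] -
                         4.0 * col[y];
            out[y] = col[y] + Dsub * lap;
          }
        }
        std::swap(a, b);
      }
      if (a != o2.data()) std::copy(a, a + NM, o2.data());
      C = o2.data();
      // consumption on occupied pixels (capped at the local level) + leak
      for (int x = 1; x < M - 1; ++x) {
        double* col = C + x * N;
        const int* gc = g + x * N;
        for (int y = 1; y < N - 1; ++y) {
          double c = col[y];
          if (gc[y] > 0) c -= (c < p.consumption) ? c : p.consumption;
          col[y] = c + p.leak * (21.0 - c) / 21.0;
        }
      }
    }

    if (p.division_on && p.division_prob > 0.0) {
      int ncell = (int)vol.size();
      for (int id = 1; id <= ncell; ++id) {
        if (vol[id - 1] < 2) continue;
        if (unif_rand() >= p.division_prob) continue;
        if (com_C(id) < p.division_cutoff) continue;
        // split: move a random half of the pixels to a new cell
        std::vector<int> pix;
        for (int q = 0; q < NM && (int)pix.size() < vol[id - 1]; ++q)
          if (g[q] == id) pix.push_back(q);
        int take = (int)pix.size() / 2;
        int newid = (int)vol.size() + 1;
        vol.push_back(0); sumx.push_back(0.0); sumy.push_back(0.0);
        lin.push_back(lin[id - 1]);
        for (int q = 0; q < take; ++q) {
          int pick = q + ri((int)pix.size() - q);
          std::swap(pix[q], pix[pick]);
          int yy = pix[q] % N, xx = pix[q] / N;
          g[pix[q]] = newid;
          vol[newid - 1] += 1; sumx[newid - 1] += xx; sumy[newid - 1] += yy;
          vol[id - 1] -= 1; sumx[id - 1] -= xx; sumy[id - 1] -= yy;
        }
      }
    }
  }

  IntegerMatrix grid_out(N, M);
  std::copy(grid.begin(), grid.end(), grid_out.begin());
  NumericMatrix o2_out(N, M);
  std::copy(o2.begin(), o2.end(), o2_out.begin());
  return List::create(_["grid"] = grid_out, _["o2"] = o2_out,
                      _["volume"] = IntegerVector(vol.begin(), vol.end()),
                      _["sumx"] = NumericVector(sumx.begin(), sumx.end()),
                      _["sumy"] = NumericVector(sumy.begin(), sumy.end()),
                      _["lineage"] = IntegerVector(lin.begin(), lin.end()));
}
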
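// Numerical kernels: ADE diffusion, ECM partitioning, CXCR7 trafficking ODEs,
// and the fused per-timestep simulation loop. Concentrations are nM, time is
// seconds, lengths are micrometers throughout.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

inline int vidx(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// One Saul'yev sweep in flux form. `up` selects the lexicographic direction.
// Already-updated neighbours (behind the sweep front) enter with their new
// values, neighbours ahead with their old values; omitting the flux on faces
// into blocked (vessel) voxels or outside the grid gives exact no-flux
// conservation.
void saulyev_sweep(const std::vector<double>& old_f, std::vector<double>& new_f,
                   int nx, int ny, int nz, const std::vector<char>& blocked,
                   double lam, bool up) {
  const int n = nx * ny * nz;
  auto cell = [&](int v) {
    if (blocked[v]) { new_f[v] = old_f[v]; return; }
    int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
    double sum_new = 0.0, sum_old = 0.0;
    int n_behind = 0, n_ahead = 0;
    const int di[3] = {1, nx, nx * ny};
    const int ci[3] = {i, j, k};
    const int cn[3] = {nx, ny, nz};
    for (int ax = 0; ax < 3; ++ax) {
      // lower neighbour
      if (ci[ax] > 0 && !blocked[v - di[ax]]) {
        if (up) { sum_new += new_f[v - di[ax]]; ++n_behind; }
        else    { sum_old += old_f[v - di[ax]]; ++n_ahead; }
      }
      // upper neighbour
      if (ci[ax] < cn[ax] - 1 && !blocked[v + di[ax]]) {
        if (up) { sum_old += old_f[v + di[ax]]; ++n_ahead; }
        else    { sum_new += new_f[v + di[ax]]; ++n_behind; }
      }
    }
    new_f[v] = (old_f[v] * (1.0 - lam * n_behind) +
                lam * (sum_new + sum_old)) / (1.0 + lam * n_ahead);
  };
  if (up) {
    for (int v = 0; v < n; ++v) cell(v);
  } else {
    for (int v = n - 1; v >= 0; --v) cell(v);
  }
}

// One full ADE step: average of the upward and downward Saul'yev sweeps.
void ade_step_inplace(std::vector<double>& f, int nx, int ny, int nz,
                      const std::vector<char>& blocked, double lam) {
  const int n = nx * ny * nz;
  std::vector<double> upf(n), dnf(n);
  saulyev_sweep(f, upf, nx, ny, nz, blocked, lam, true);
  saulyev_sweep(f, dnf, nx, ny, nz, blocked, lam, false);
  for (int v = 0; v < n; ++v) f[v] = 0.5 * (upf[v] + dnf[v]);
}

struct TraffickPars {
  double kon, koff, kint, kint0, krec, kdegL, qsyn;
};

// RHS of the per-cell trafficking system, states:
// 0 Rs surface receptor, 1 Cs surface complex, 2 Ri internal receptor,
// 3 Ci internal complex, 4 Ldeg cumulative degraded ligand,
// 5 U cumulative net ligand removed from the voxel (all receptor counts).
inline void trhs(const double* y, double* dy, double L, const TraffickPars& p) {
  const double bind = p.kon * L * y[0];
  dy[0] = -bind + p.koff * y[1] - p.kint0 * y[0] + p.krec * y[2] + p.qsyn;
  dy[1] = bind - (p.koff + p.kint) * y[1];
  // receptor is recycled to the internal pool when its ligand is degraded,
  // so the receptor pool is conserved and scavenging is sustained
  dy[2] = p.kint0 * y[0] - p.krec * y[2] + p.kdegL * y[3];
  dy[3] = p.kint * y[1] - p.kdegL * y[3];
  dy[4] = p.kdegL * y[3];
  dy[5] = bind - p.koff * y[1];
}

// Classical RK4 with a positivity floor; L held constant over dt.
// Returns the net ligand removal (receptor counts, may be negative if the
// cell releases previously bound ligand).
double rk4_cell(double* y, double L, const TraffickPars& p, double dt,
                double hmax) {
  int nsub = (int)std::ceil(dt / hmax);
  if (nsub < 1) nsub = 1;
  const double h = dt / nsub;
  double k1[6], k2[6], k3[6], k4[6], ytmp[6];
  const double U0 = y[5];
  for (int s = 0; s < nsub; ++s) {
    trhs(y, k1, L, p);
    for (int m = 0; m < 6; ++m) ytmp[m] = y[m] + 0.5 * h * k1[m];
    trhs(ytmp, k2, L, p);
    for (int m = 0; m < 6; ++m) ytmp[m] = y[m] + 0.5 * h * k2[m];
    trhs(ytmp, k3, L, p);
    for (int m = 0; m < 6; ++m) ytmp[m] = y[m] + h * k3[m];
    trhs(ytmp, k4, L, p);
    for (int m = 0; m < 6; ++m) {
      y[m] += h / 6.0 * (k1[m] + 2.0 * k2[m] + 2.0 * k3[m] + k4[m]);
      if (m < 5 && y[m] < 0.0) y[m] = 0.0;
    }
  }
  return y[5] - U0;
}

inline double substep_bound(double L, const TraffickPars& p) {
  double r = p.kon * L + p.kint0;
  r = std::max(r, p.koff + p.kint);
  r = std::max(r, p.krec);
  r = std::max(r, p.kdegL);
  if (r <= 0.0) return 1e9;
  return std::min(0.05, 0.2 / r);
}

TraffickPars as_pars(const List& tp) {
  TraffickPars p;
  p.kon = as<double>(tp["k_on"]);
  p.koff = as<double>(tp["k_off"]);
  p.kint = as<double>(tp["k_int"]);
  p.kint0 = as<double>(tp["k_int0"]);
  p.krec = as<double>(tp["k_rec"]);
  p.kdegL = as<double>(tp["k_degL"]);
  p.qsyn = as<double>(tp["q_syn"]);
  return p;
}

// Circadian cosine, t in hours.
inline double circadian(double t_h, double x_max, double x_min, double f,
                        double phase0_h) {
  return 0.5 * (x_max - x_min) * std::cos(2.0 * M_PI * f * (t_h - phase0_h)) +
         0.5 * (x_max + x_min);
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_ade_step(NumericVector field, IntegerVector dims,
                           LogicalVector blocked, double lam, int n_steps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<double> f(field.begin(), field.end());
  std::vector<char> blk(n, 0);
  if (blocked.size() == n)
    for (int v = 0; v < n; ++v) blk[v] = blocked[v] ? 1 : 0;
  for (int s = 0; s < n_steps; ++s) ade_step_inplace(f, nx, ny, nz, blk, lam);
  NumericVector out(f.begin(), f.end());
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
List cpp_trafficking_step(NumericMatrix state, NumericVector L, List tpars,
                          double dt) {
  const TraffickPars p = as_pars(tpars);
  const int n = state.nrow();
  NumericMatrix out(clone(state));
  NumericVector uptake(n);
  for (int c = 0; c < n; ++c) {
    double y[6];
    for (int m = 0; m < 6; ++m) y[m] = (m < 5) ? out(c, m) : 0.0;
    const double hmax = substep_bound(L[c], p);
    uptake[c] = rk4_cell(y, L[c], p, dt, hmax);
    for (int m = 0; m < 5; ++m) out(c, m) = y[m];
  }
  return List::create(_["state"] = out, _["uptake_counts"] = uptake);
}

// Fused simulation loop. Per step:
//   secretion + vessel exchange -> diffusion -> extracellular degradation ->
//   ECM exchange -> receptor-mediated uptake.
// Mode codes for secretion/blood forcing: 0 = held at the circadian value at
// t_start (stage-1 initialization), 1 = circadian, 2 = constant at the mean.
// [[Rcpp::export]]
List cpp_run_sim(NumericVector free0, NumericVector bound0, IntegerVector dims,
                 LogicalVector vessel_mask, double lam, double dt,
                 double k_deg, double k_on_ecm, double K_p,
                 IntegerVector secr_vox,
                 double S_max, double S_min, int S_mode,
                 IntegerVector scav_vox, NumericMatrix scav_state, List tpars,
                 double mol_per_nM,
                 IntegerVector exch_vox, NumericVector exch_A, double perm,
                 double vox_vol_um3,
                 double Cb_max, double Cb_min, int Cb_mode,
                 double circ_f, double phase0_h, double t_start_h,
                 double t0_s, int n_steps, int record_every,
                 List record_sets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<double> F(free0.begin(), free0.end());
  std::vector<double> B(bound0.begin(), bound0.end());
  std::vector<char> blk(n, 0);
  if (vessel_mask.size() == n)
    for (int v = 0; v < n; ++v) blk[v] = vessel_mask[v] ? 1 : 0;

  const TraffickPars tp = as_pars(tpars);
  NumericMatrix cstate(clone(scav_state));
  const int n_secr = secr_vox.size();
  const int n_scav = scav_vox.size();
  const int n_exch = exch_vox.size();
  const int n_sets = record_sets.size();

  // precompute record-set index vectors
  std::vector<std::vector<int> > sets(n_sets);
  for (int s = 0; s < n_sets; ++s) {
    IntegerVector iv = record_sets[s];
    sets[s].assign(iv.begin(), iv.end());
  }

  const double deg_fac = std::exp(-k_deg * dt);
  const double k_off_ecm = (K_p > 0.0) ? k_on_ecm / K_p : 0.0;
  const double ecm_rate = k_on_ecm + k_off_ecm;
  const double ecm_fac = std::exp(-ecm_rate * dt);
  const double beq_frac = (ecm_rate > 0.0) ? k_on_ecm / ecm_rate : 0.0;

  double cum_secreted = 0.0, cum_degraded = 0.0, cum_scavenged = 0.0,
         cum_exchanged = 0.0;
  long clip_events = 0;

  const int n_rec = (record_every > 0) ? n_steps / record_every : 0;
  const int n_cols = 4 + n_sets + 2; // time_h, C_blood, S, sets..., massF, massB, clip
  NumericMatrix rec(n_rec, 3 + n_sets + 3);
  (void)n_cols;
  int rec_row = 0;

  for (int step = 0; step < n_steps; ++step) {
    const double t_s = t0_s + step * dt;
    const double t_h = t_s / 3600.0;

    // forcing values for this step
    double S_t;
    if (S_mode == 1)      S_t = circadian(t_h, S_max, S_min, circ_f, phase0_h);
    else if (S_mode == 0) S_t = circadian(t_start_h, S_max, S_min, circ_f, phase0_h);
    else                  S_t = 0.5 * (S_max + S_min);
    double Cb_t;
    if (Cb_mode == 1)      Cb_t = circadian(t_h, Cb_max, Cb_min, circ_f, phase0_h);
    else if (Cb_mode == 0) Cb_t = circadian(t_start_h, Cb_max, Cb_min, circ_f, phase0_h);
    else                   Cb_t = 0.5 * (Cb_max + Cb_min);

    // 1. secretion
    const double dsec = S_t * dt / mol_per_nM;
    for (int c = 0; c < n_secr; ++c) F[secr_vox[c]] += dsec;
    cum_secreted += dsec * n_secr;

    // 2. transvascular exchange (free ligand only); blood is a reservoir
    for (int m = 0; m < n_exch; ++m) {
      const int v = exch_vox[m];
      const double dC = perm * exch_A[m] * dt * (Cb_t - F[v]) / vox_vol_um3;
      F[v] += dC;
      cum_exchanged += dC;
    }

    // 3. diffusion of the free field
    if (lam > 0.0) ade_step_inplace(F, nx, ny, nz, blk, lam);

    // 4. extracellular degradation (free ligand only; ECM-bound protected)
    if (k_deg > 0.0) {
      for (int v = 0; v < n; ++v) {
        const double loss = F[v] * (1.0 - deg_fac);
        F[v] -= loss;
        cum_degraded += loss;
      }
    }

    // 5. ECM exchange: exact exponential relaxation to B/F = K_p
    if (k_on_ecm > 0.0 && K_p > 0.0) {
      for (int v = 0; v < n; ++v) {
        if (blk[v]) continue;
        const double tot = F[v] + B[v];
        const double beq = tot * beq_frac;
        B[v] = beq + (B[v] - beq) * ecm_fac;
        F[v] = tot - B[v];
      }
    }

    // 6. receptor-mediated uptake (sees free + bound, removes pro rata)
    for (int c = 0; c < n_scav; ++c) {
      const int v = scav_vox[c];
      const double Lav = F[v] + B[v];
      double y[6];
      for (int m = 0; m < 5; ++m) y[m] = cstate(c, m);
      y[5] = 0.0;
      const double hmax = substep_bound(Lav, tp);
      double dL = rk4_cell(y, Lav, tp, dt, hmax) / mol_per_nM;
      for (int m = 0; m < 5; ++m) cstate(c, m) = y[m];
      if (dL > Lav) { dL = Lav; ++clip_events; }
      if (Lav > 0.0) {
        const double fr = F[v] / Lav;
        F[v] -= dL * fr;
        B[v] -= dL * (1.0 - fr);
        if (F[v] < 0.0) F[v] = 0.0;
        if (B[v] < 0.0) B[v] = 0.0;
      }
      cum_scavenged += dL;
    }

    // recording
    if (record_every > 0 && (step + 1) % record_every == 0 && rec_row < n_rec) {
      const double t_end_h = (t0_s + (step + 1) * dt) / 3600.0;
      rec(rec_row, 0) = t_end_h;
      rec(rec_row, 1) = Cb_t;
      rec(rec_row, 2) = S_t;
      for (int s = 0; s < n_sets; ++s) {
        double acc = 0.0;
        for (size_t q = 0; q < sets[s].size(); ++q) {
          const int v = sets[s][q];
          acc += F[v] + B[v];
        }
        rec(rec_row, 3 + s) = sets[s].empty() ? NA_REAL : acc / sets[s].size();
      }
      double mF = 0.0, mB = 0.0;
      for (int v = 0; v < n; ++v) { mF += F[v]; mB += B[v]; }
      rec(rec_row, 3 + n_sets) = mF;
      rec(rec_row, 4 + n_sets) = mB;
      rec(rec_row, 5 + n_sets) = (double)clip_events;
      ++rec_row;
    }
  }

  NumericVector Fout(F.begin(), F.end()), Bout(B.begin(), B.end());
  Fout.attr("dim") = dims;
  Bout.attr("dim") = dims;
  return List::create(
      _["free"] = Fout, _["bound"] = Bout, _["scav_state"] = cstate,
      _["records"] = rec, _["time_s"] = t0_s + (double)n_steps * dt,
      _["cum_secreted"] = cum_secreted, _["cum_degraded"] = cum_degraded,
      _["cum_scavenged"] = cum_scavenged, _["cum_exchanged"] = cum_exchanged,
      _["clip_events"] = (double)clip_events);
}
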
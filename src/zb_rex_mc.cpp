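#include <Rcpp.h>
using namespace Rcpp;

// Zimm-Bragg statistical weight of the helix state at temperature T,
// anchored so the propagation weight s equals 1 at Tref.
static inline double zb_s(double dH, double Tref, double T, double Rgas) {
  return std::exp(-(dH / Rgas) * (1.0 / T - 1.0 / Tref));
}

// Metropolis single-spin-flip replica-exchange sampler of a helix/coil
// chain. Configurations carry weight sigma^(segments) * s^(n_helix); the
// recorded per-frame energy is dH * n_helix, which together with the
// anchoring of s at Tref makes sampling exactly Boltzmann in that energy
// (the Tref-dependent factor is temperature independent and belongs to
// the density of states). Uses R's RNG stream, so results are
// reproducible under set.seed().
// [[Rcpp::export(name = ".zb_rex_mc")]]
List zb_rex_mc(int n_res, double sigma, double dH, double Tref,
               NumericVector ladder, int frames, int exchange_period,
               int equil_sweeps, double rg_helix, double rg_coil,
               double rg_noise, double Rgas) {
  const int K = ladder.size();
  // helix[k][i]: state of residue i in replica k (1 = helix, 0 = coil)
  std::vector<std::vector<int>> helix(K, std::vector<int>(n_res, 0));
  std::vector<int> n_h(K, 0);
  // temp_of_replica[k] = index into ladder; replica_at_temp inverse map
  std::vector<int> temp_of_replica(K), replica_at_temp(K);
  for (int k = 0; k < K; ++k) {
    temp_of_replica[k] = k;
    replica_at_temp[k] = k;
    for (int i = 0; i < n_res; ++i) {
      helix[k][i] = (unif_rand() < 0.5) ? 1 : 0;
      n_h[k] += helix[k][i];
    }
  }
  std::vector<double> s_at(K);
  for (int k = 0; k < K; ++k) s_at[k] = zb_s(dH, Tref, ladder[k], Rgas);

  const int n_frames_total = frames * K;
  IntegerVector f_step(n_frames_total), f_replica(n_frames_total);
  NumericVector f_temp(n_frames_total), f_energy(n_frames_total),
      f_rg(n_frames_total), f_helix(n_frames_total);
  std::vector<int> x_step, x_a, x_b, x_acc;

  int out = 0;
  int exchange_phase = 0;
  const int total_sweeps = equil_sweeps + frames;
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int k = 0; k < K; ++k) {
      const double s = s_at[temp_of_replica[k]];
      std::vector<int> &h = helix[k];
      for (int a = 0; a < n_res; ++a) {
        int i = (int)(unif_rand() * n_res);
        if (i >= n_res) i = n_res - 1;
        const int left = (i > 0) ? h[i - 1] : 0;
        const int right = (i < n_res - 1) ? h[i + 1] : 0;
        const int dn = h[i] ? -1 : 1;          // flip direction
        const int dseg = dn * (1 - left - right);
        const double ratio = std::pow(s, dn) * std::pow(sigma, dseg);
        if (ratio >= 1.0 || unif_rand() < ratio) {
          h[i] = 1 - h[i];
          n_h[k] += dn;
        }
      }
    }
    const bool recording = sweep >= equil_sweeps;
    const int step = sweep - equil_sweeps + 1;
    if (recording) {
      for (int k = 0; k < K; ++k) {
        f_step[out] = step;
        f_replica[out] = k + 1;
        f_temp[out] = ladder[temp_of_replica[k]];
        f_energy[out] = dH * n_h[k];
        const double th = (double)n_h[k] / n_res;
        f_helix[out] = th;
        f_rg[out] = rg_coil - (rg_coil - rg_helix) * th +
                    rg_noise * norm_rand();
        ++out;
      }
    }
    // adjacent-pair swap attempts, alternating even/odd phase
    if (K >= 2 && exchange_period > 0 &&
        (sweep + 1) % exchange_period == 0) {
      for (int t = exchange_phase; t + 1 < K; t += 2) {
        const int ri = replica_at_temp[t];      // lower temperature
        const int rj = replica_at_temp[t + 1];  // higher temperature
        const double Ei = dH * n_h[ri];
        const double Ej = dH * n_h[rj];
        const double bi = 1.0 / (Rgas * ladder[t]);
        const double bj = 1.0 / (Rgas * ladder[t + 1]);
        const double darg = (bi - bj) * (Ei - Ej);
        const bool acc = (darg >= 0.0) || (unif_rand() < std::exp(darg));
        if (recording) {
          x_step.push_back(step);
          x_a.push_back(ri + 1);
          x_b.push_back(rj + 1);
          x_acc.push_back(acc ? 1 : 0);
        }
        if (acc) {
          temp_of_replica[ri] = t + 1;
          temp_of_replica[rj] = t;
          replica_at_temp[t] = rj;
          replica_at_temp[t + 1] = ri;
        }
      }
      exchange_phase = 1 - exchange_phase;
    }
  }

  return List::create(
      _["step"] = f_step, _["replica_id"] = f_replica,
      _["temperature_K"] = f_temp, _["energy_kcal_mol"] = f_energy,
      _["rg_angstrom"] = f_rg, _["helix_fraction"] = f_helix,
      _["x_step"] = wrap(x_step), _["x_a"] = wrap(x_a),
      _["x_b"] = wrap(x_b), _["x_acc"] = wrap(x_acc));
}
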
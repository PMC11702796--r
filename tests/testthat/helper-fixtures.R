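# Shared fixture builders. Everything is generated in code; no data files.

# Signal curve straight from the thermal model (no spectra involved).
make_thermal_curve <- function(dH_app = 50, Tm_K = 333, Yn = 100, Yd = -60,
                               x = seq(293, 363, by = 5), noise_sd = 0,
                               seed = 1L) {
  y <- eval_thermal_model(dH_app, Tm_K, Yn, Yd, x)
  if (noise_sd > 0)
    y <- y + withr::with_seed(seed, stats::rnorm(length(x), sd = noise_sd))
  signal_curve(x, y, "peak_intensity", "temperature", "unfolding")
}

make_chemical_curve <- function(dG_app = 4, m_value = 2, Yn = 330, Yd = 20,
                                T_K = 298.15, x = seq(0, 4, by = 0.25),
                                noise_sd = 0, seed = 1L) {
  y <- eval_chemical_model(dG_app, m_value, Yn, Yd, T_K, x)
  if (noise_sd > 0)
    y <- y + withr::with_seed(seed, stats::rnorm(length(x), sd = noise_sd))
  signal_curve(x, y, "lambda_max", "denaturant", "unfolding")
}

# Exact Boltzmann sampler for a two-level system (energies 0 and -dE, both
# non-degenerate): P(-dE) = e^(b dE) / (1 + e^(b dE)) at inverse
# temperature b = 1/(R T). Used as the independent oracle for WHAM.
make_two_level_dataset <- function(dE = 1.5, temps = c(280, 300, 320, 340),
                                   n_per_temp = 4000L, seed = 1L) {
  frames <- withr::with_seed(seed, {
    do.call(rbind, lapply(temps, function(temp) {
      p_low <- stats::plogis(dE / (R_gas * temp))
      low <- stats::rbinom(n_per_temp, 1L, p_low)
      data.frame(step = seq_len(n_per_temp), replica_id = match(temp, temps),
                 temperature_K = temp, energy_kcal_mol = -dE * low,
                 rg_angstrom = 15 + low, helix_fraction = 0.5)
    }))
  })
  rex_dataset(frames)
}

# Minimal hand-built WHAM solution for closed-form checks of the
# reweighting stages (bypasses sampling entirely).
make_exact_wham <- function(energies, ln_omega, temperatures = c(100, 500)) {
  structure(
    list(bin_centers = energies, bin_width = diff(range(energies)),
         ln_omega = ln_omega - ln_omega[1], temperatures = temperatures,
         f_k = rep(0, length(temperatures)),
         n_frames = rep(1, length(temperatures)),
         iterations = 0L, residual = 0, converged = TRUE),
    class = "wham_solution")
}

# Closed-form independent-site (sigma = 1) Zimm-Bragg thermodynamics.
independent_site_oracle <- function(config, T_K) {
  u <- (config$dH_prop / R_gas) * (1 / T_K - 1 / config$Tref_K)
  theta <- 1 / (1 + exp(u))
  list(
    helix_fraction = theta,
    E_mean = config$dH_prop * config$n_res * theta,
    Cv = config$n_res * config$dH_prop^2 / (R_gas * T_K^2) *
      exp(u) / (1 + exp(u))^2
  )
}

# Analytic Cv-peak temperature of a Zimm-Bragg config.
analytic_cv_peak <- function(config, lower = 300, upper = 380) {
  stats::optimize(function(x) -zimm_bragg_analytic(config, x)$Cv,
                  c(lower, upper))$minimum
}

tiny_spectra_series <- function(n_cond = 8L, noise_sd = 0, seed = 0L,
                                mode = "thermal") {
  conds <- if (mode == "thermal") seq(293, 363, length.out = n_cond)
           else seq(0, 4, length.out = n_cond)
  simulate_spectra_series(
    spectra_sim_config(mode, conditions = conds, noise_sd = noise_sd,
                       seed = seed))
}
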
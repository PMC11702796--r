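# stabscan

Quantifying how missense mutations change protein stability, and
condensing heterogeneous evidence into one consensus score per mutation.

Point mutations in folded domains shift the melting temperature, the
chemical-denaturation midpoint, the simulated heat-capacity peak, and
the outputs of ΔΔG predictor tools — four kinds of evidence on four
different scales. `stabscan` is for structural biologists and protein
biophysicists who have some or all of these measurements and want them
fitted, converted to a common free-energy scale, and aggregated
reproducibly:

* **Two-state denaturation fits.** Thermal scans are fitted with the
  van't Hoff sigmoid
  `y = Yn + Yd·e^u/(1+e^u)`, `u = (ΔH_app/R)(1/Tm − 1/T)`,
  and chemical titrations with the linear-extrapolation form
  `v = −(ΔG_app − m·x)/(RT)` (midpoint `D½ = ΔG_app/m`), from
  fluorescence spectra series via configurable observable channels
  (λmax, peak intensity, integrated intensity).
* **Replica-exchange thermodynamics.** Multi-temperature trajectories
  are combined by the weighted histogram analysis method (WHAM) into a
  density of states; from it: `⟨E⟩(T)`, `Cv(T) = (⟨E²⟩−⟨E⟩²)/(RT²)`,
  the melting temperature (Cv peak), potential-of-mean-force landscapes
  `−RT ln P` over Rg × helix fraction, Rg melting sigmoids, and
  exchange-acceptance diagnostics.
* **Impact scoring.** Every effect becomes kcal/mol
  (`ΔΔG ≈ ΔHm·ΔTm/Tm` for melting shifts, `ΔΔG ≈ m·ΔD½` for chemical
  shifts), and per mutation the four absolute components are summed and
  divided by the largest such sum, so the most affected mutation scores
  exactly 1. Agreement with reference pathogenicity scores is reported
  as a Pearson correlation.
* **Synthetic ground truth.** A two-band Gaussian spectra generator and
  a Metropolis-sampled Zimm–Bragg helix–coil chain (with an exact
  transfer-matrix solution) give every estimator an oracle; both are
  first-class, seeded, deterministic simulators.

All energies are molar (kcal/mol; `R_gas = kB_molar = 1.9872e-3`
kcal/(mol·K)).

## Worked example

```r
library(stabscan)

# simulate a thermal unfolding experiment (ground truth: Tm 333 K,
# dH_app 50 kcal/mol) and fit it
ser <- simulate_spectra_series(spectra_sim_config("thermal", noise_sd = 0.5, seed = 1))
ser
#> <denaturation_series> 15 spectra (temperature, unfolding)
#>   wavelengths: 290-360 nm (71 points)
#>   conditions:  293-363 K
fit_thermal(build_signal_curve(ser, "integrated_intensity"))
#> <thermal_fit> Tm = 332.93 K, dH_app = 49.99 kcal/mol (integrated_intensity, unfolding)

# full synthetic cohort: WT + four mutants of graded severity
report <- run_pipeline(
  run_config(list(seed = 1, channel_thermal = "integrated_intensity",
                  channel_chemical = "integrated_intensity")),
  synthetic = TRUE, verbose = FALSE)
report$impact[, c("mutation", "sum_abs", "overall_impact")]
#>   mutation    sum_abs overall_impact
#> 1     mutA  0.8897553     0.08493178
#> 2     mutB  2.9574426     0.28230331
#> 3     mutC  6.8268720     0.65166050
#> 4     mutD 10.4761174     1.00000000
report$pearson$r
#> [1] 0.9979736
```

The fitted melting temperature lands on the 333 K ground truth to
0.1 K; the mutant engineered to be most destabilizing (`mutD`, ΔTm
10 K, ΔD½ 0.8 M) gets overall impact exactly 1 (it sets the scaling
factor, here 10.48 kcal/mol), and the score ordering matches the
built-in reference scores (Pearson r ≈ 1 on this clean synthetic
cohort).

A thin command-line front end over the same functions lives in
`inst/cli/stabscan.R`:

```sh
Rscript inst/cli/stabscan.R simulate-rex --seed 3 --frames 5000 \
    --out traj.tsv --exchange-log xlog.tsv
Rscript inst/cli/stabscan.R wham --traj traj.tsv --exchange-log xlog.tsv --out wham_out/
Rscript inst/cli/stabscan.R run --synthetic --seed 7 --out run_out/
```

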
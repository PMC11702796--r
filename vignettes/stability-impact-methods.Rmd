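---
title: "Quantifying mutation effects on protein stability: models and methods"
author: "stabscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mutation effects on protein stability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabscan)
```

# Overview

`stabscan` measures how missense mutations change the stability of a
protein domain and condenses heterogeneous evidence — machine-learning
predictors, replica-exchange simulations, thermal denaturation and
chemical denaturation — into a single normalized impact score per
mutation. This vignette is the package's own account of the models it
fits, the estimators it implements, the synthetic data it validates
against, and the design choices that were genuinely open.

All energies in the package are molar: the gas constant
`R_gas = 1.9872e-3` kcal/(mol K) doubles as the Boltzmann constant
(`kB_molar`), heat capacities are kcal/(mol K), free energies kcal/mol.

# Two-state denaturation models

Intrinsic (tryptophan) fluorescence reports on unfolding: the emission
band red-shifts and loses intensity as the protein unfolds. A spectra
series (one emission spectrum per temperature or denaturant
concentration) is reduced to a *signal curve* — one observable per
condition — and fitted with a two-state sigmoid.

**Thermal** (`fit_thermal()`, model `eval_thermal_model()`):

$$y(T) = Y_n + Y_d\,\frac{e^{u}}{1+e^{u}},\qquad
u = \frac{\Delta H_\mathrm{app}}{R}\left(\frac{1}{T_m}-\frac{1}{T}\right)$$

**Chemical** (`fit_chemical()`, model `eval_chemical_model()`):

$$y(x) = Y_n + Y_d\,\frac{e^{v}}{1+e^{v}},\qquad
v = -\frac{\Delta G_\mathrm{app} - m\,x}{R\,T}$$

with midpoint $D_{1/2}=\Delta G_\mathrm{app}/m$, the denaturant
concentration at which half the native signal is lost.

Conventions and caveats:

* $Y_d$ is the **transition amplitude**: the post-transition level is
  $Y_n + Y_d$, and the model value at the midpoint is exactly
  $Y_n + Y_d/2$. (Captions elsewhere sometimes call $Y_n$/$Y_d$ the pre-
  and post-transition levels; the algebra above is what is fitted.)
* Baselines are condition-independent constants; no sloped baselines, no
  three-state models.
* Thermal unfolding of this kind of domain is typically irreversible, so
  $T_m$ and $\Delta H_\mathrm{app}$ are *apparent* quantities; no
  equilibrium-thermodynamic claims are attached to them.
* The chemical fit temperature is fixed at 298.15 K (room temperature),
  configurable via `fit_chemical(..., T_K = )`.

**Fitting.** Nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`). Initialization is deterministic: $Y_n$ from the first
three points, the post level from the last three, the midpoint from the
linear-interpolated half-signal crossing, $\Delta H_\mathrm{app}$
starting at 50 kcal/mol and $m$ at 2 kcal/(mol M); up to five
deterministic multi-start restarts jitter the initials by ±30% before a
fit is flagged non-converged (flagged fits still report parameters).
Standard errors come from the Jacobian. Curves whose signal range does
not exceed five times the median successive difference are rejected as
degenerate transitions rather than fitted.

**Observable channels.** Three channels are supported:
`lambda_max` (peak wavelength by parabolic interpolation through the
maximal sample and its neighbours), `peak_intensity` (interpolated
intensity at that peak) and `integrated_intensity` (trapezoidal integral
over the emission window). Defaults follow common practice — wavelength
shift for chemical titrations, intensity for thermal scans — but only
the integrated intensity is an *affine* function of the unfolded
fraction when the native and unfolded emission bands overlap. The peak
channels are mildly nonlinear in the unfolded fraction, which shifts
apparent midpoints by a few percent (systematically, and nearly equally
for all variants measured with the same bands, so *differences* between
variants are much less affected). The peak-intensity channel is not even
guaranteed monotone: past the band crossover the spectrum maximum jumps
from the decaying native band to the weaker unfolded band and partially
recovers. Parameter-recovery guarantees are therefore stated for the
integrated-intensity channel.

**Stability deltas** (`stability_deltas()`): $\Delta T_m = T_{m,WT} -
T_{m,\mathrm{mut}}$; per-variant hysteresis $\Delta D_{1/2} =
D_{1/2,\mathrm{unf}} - D_{1/2,\mathrm{ref}}$; $\Delta\Delta D_{1/2} =
\Delta D_{1/2,WT} - \Delta D_{1/2,\mathrm{mut}}$; and the
unfolding-midpoint shift $D_{1/2,\mathrm{unf},WT} -
D_{1/2,\mathrm{unf,mut}}$. Positive values mean destabilizing.

# Replica-exchange thermodynamics

The analysis layer consumes per-frame observables (energy, radius of
gyration, helix fraction) from replicas run at a ladder of temperatures
with Metropolis swaps, and estimates equilibrium thermodynamics at any
temperature by the weighted histogram analysis method (WHAM,
`wham_solve()`):

$$\Omega(E_b) = \frac{\sum_k n_k(E_b)}
{\sum_k N_k\, e^{f_k - E_b/(R T_k)}},\qquad
e^{-f_k} = \sum_b \Omega(E_b)\, e^{-E_b/(R T_k)}$$

iterated to self-consistency (tolerance $10^{-7}$ on $\max|\Delta f_k|$,
at most 10,000 iterations, log-sum-exp arithmetic throughout, $f_1$
pinned to zero). Energies are binned into 200 equal-width bins by
default; each occupied bin is represented by the **mean energy of its
frames** rather than its geometric centre — for systems with discrete
energy levels (such as the synthetic chain below) this removes a
reweighting bias of order the bin width, and for continuous energies it
is a strictly better one-point quadrature. Empty bins carry zero density
and are never smoothed.

No autocorrelation or statistical-inefficiency correction is applied:
frames carry uniform weight within a temperature. This is a documented
limitation — naive per-run standard errors computed from such weights
underestimate the true run-to-run spread by a factor of roughly 2–4 for
the synthetic system, which is why the package's own validation averages
over independent runs (and `reweight_observable(se = TRUE)` uses
contiguous-block means, a partial mitigation).

Derived quantities:

* `compute_cv()`: canonical $\langle E\rangle(T)$ and
  $C_v(T) = (\langle E^2\rangle - \langle E\rangle^2)/(R T^2)$ on a
  0.5 K grid; the melting temperature is the $C_v$ peak, refined by a
  parabola through the peak and its neighbours. Temperatures more than
  25 K outside the ladder are refused (extrapolation).
* `compute_pmf()`: free-energy landscape $-RT\ln P$ over one or two
  order parameters (default $R_g$ versus helix fraction, 50 bins each),
  with the minimum anchored at zero and unreachable bins at $+\infty$.
* `rg_melting_fit()`: the reweighted $\langle R_g\rangle(T)$ fitted with
  the thermal sigmoid — an independent melting-midpoint estimate.
* `exchange_rate_summary()`: acceptance per adjacent temperature pair,
  attributed via the frames to the temperatures held at the attempt.
* `delta_tm()`: $T_m$ shifts versus wild type, same sign convention as
  the experimental $\Delta T_m$.

# The synthetic systems and what they do (not) show

Every estimator is validated against synthetic data with exact ground
truth.

**Spectra** (`simulate_spectra_series()`): each condition's spectrum is
$(1-f_u)\,G_n(\lambda) + f_u\,G_u(\lambda)$ plus i.i.d. Gaussian noise,
where $f_u$ is the two-state unfolded fraction and $G_n$, $G_u$ are
Gaussian emission bands (native 330 nm/amplitude 100, unfolded
350 nm/amplitude 60, emission window 290–360 nm). Gaussian band shapes
are the simplest choice preserving the two observables the analysis
uses (peak position and intensity). Defaults emulate the study
conditions: thermal scans 293–363 K in 5 K steps with $T_m = 333$ K and
$\Delta H_\mathrm{app} = 50$ kcal/mol; titrations 0–4 M in 0.25 M steps
with $\Delta G_\mathrm{app} = 4$ kcal/mol, $m = 2$ kcal/(mol M)
($D_{1/2} = 2$ M). What this generator does *not* emulate: sloped
baselines, aggregation kinetics, photobleaching, correlated noise, or
the low-concentration intensity rise sometimes seen at the start of
titrations; passing recovery tests therefore demonstrates estimator
correctness, not robustness to every artefact of real spectra.

**Replica exchange** (`simulate_rex_zimm_bragg()`): a Zimm–Bragg
helix–coil chain sampled by Metropolis single-spin flips. A
configuration with $n$ helical residues in $g$ contiguous segments has
weight $\sigma^{g} s(T)^{n}$ with
$s(T) = \exp[-(\Delta H_\mathrm{prop}/R)(1/T - 1/T_\mathrm{ref})]$,
where $\Delta H_\mathrm{prop} < 0$ is the helix propagation enthalpy
(so the chain is helical at low temperature and melts on heating). The
recorded energy is $\Delta H_\mathrm{prop}\times n$, which makes the
sampled distribution exactly Boltzmann in that energy: the
$T_\mathrm{ref}$-dependent factor of $s^n$ is temperature-independent
and belongs to the density of states. Swaps between adjacent
temperatures (alternating even/odd pairings every `exchange_period`
sweeps) are accepted with probability
$\min\{1, \exp[(\beta_i-\beta_j)(E_i-E_j)]\}$. The Rg channel is an
affine map of the helix fraction
($R_{g,\mathrm{coil}} \to R_{g,\mathrm{helix}}$) plus Gaussian noise —
a caricature of compaction, not a geometric model; absolute Rg values of
a real domain are out of scope.

The chain admits an exact transfer-matrix solution
(`zimm_bragg_analytic()`): helix fraction $(1/N)\,s\,\partial\ln
Z/\partial s$ by derivative propagation through the normalized 2×2
recursion, mean energy $\Delta H_\mathrm{prop} N \theta$, and $C_v$ by a
centred 0.01 K finite difference. At $\sigma = 1$ residues are
independent and everything collapses to closed form:
$\theta = 1/(1+e^{u})$,
$C_v = N \Delta H_\mathrm{prop}^2/(R T^2)\; e^{u}/(1+e^{u})^2$ with
$u = (\Delta H_\mathrm{prop}/R)(1/T-1/T_\mathrm{ref})$. These are the
oracles behind the WHAM, $C_v$ and PMF tests.

**Default parameters** (chosen once, as the package's study
conditions): $N = 30$ residues, $\sigma = 1$,
$\Delta H_\mathrm{prop} = -20$ kcal/mol, $T_\mathrm{ref} = 340$ K, eight
replicas evenly spaced over 300–380 K, 20,000 recorded frames per
replica after 1,000 equilibration sweeps, exchange attempts every 10
sweeps. The per-residue enthalpy is an *effective coarse-grained*
parameter, not a physical residue-level value: it is set so that the
whole melting transition (helix fraction 0.97 → 0.03) is resolved inside
the ladder, the $C_v$ peak (analytically 338.46 K) is interior to the
grid, and the $C_v$-peak and Rg-melt midpoint (340 K) agree to ~1.5 K as
they should for a quasi-two-state system. A physically realistic
per-residue enthalpy (~1 kcal/mol) with $\sigma = 1$ would spread the
transition over hundreds of kelvin and push the $C_v$ maximum to the
grid edge, validating nothing. A consequence worth knowing: the sharp
transition makes mid-ladder swap acceptance dip to ~5% with eight
replicas — harmless here (WHAM needs per-temperature equilibrium, which
single-temperature dynamics already provide; swaps only decorrelate),
and the acceptance-versus-spacing diagnostics use narrower two-replica
ladders where rates span (0, 1].

**Determinism.** One global seed drives everything through R's RNG,
which the C++ sampling kernel also consumes; runs are single-threaded,
so a seed reproduces every dataset bit for bit. (Per-replica counter
streams would only matter for parallel execution, which the kernel does
not do.)

# From effects to a common scale: the impact score

Every stability effect is converted to kcal/mol:

* Melting-shift routes (`ddg_from_tm_shift()`):
  $\Delta\Delta G \approx \Delta H_m\,\Delta T_m / T_m$. The simulation
  route takes $\Delta H_m$ from the $C_v$ peak integral
  (`cv_peak_enthalpy()`: area above the half-maximum baseline between
  the two half-maximum temperatures) and $T_m$ from the wild-type $C_v$
  peak; the thermal-denaturation route takes the fitted wild-type
  $\Delta H_\mathrm{app}$ and $T_m$. The formulas are identical; only
  the provenance differs.
* Chemical route (`ddg_from_chemical()`):
  $\Delta\Delta G \approx m\,\Delta D_{1/2}$ with the wild-type
  unfolding $m$-value. By default $\Delta D_{1/2}$ is the
  wild-type-minus-mutant shift of the *unfolding* midpoint (the
  mutant-versus-reference comparison the score needs); the
  unfolding-versus-refolding hysteresis is reported separately and can
  be selected instead via the `chemical_delta = "hysteresis"` option.
* Predictor table: multiple tools' $\Delta\Delta G$ values reduce to one
  per mutation (`aggregate_predictor_ddg()`), by unweighted mean by
  default (median or a single named tool are alternatives) — with no
  stated reduction rule, the mean is the unbiased default.

The overall impact (`overall_impact()`) of mutation $i$ is

$$\mathrm{Impact}_i = \frac{|\Delta\Delta G_{PT,i}| +
|\Delta\Delta G_{rex,i}| + |\Delta\Delta G_{TD,i}| +
|\Delta\Delta G_{CD,i}|}{\max_j \sum |\Delta\Delta G_{\cdot,j}|}$$

Absolute values mean stabilizing and destabilizing shifts both raise the
score — it measures magnitude of impact, not direction. The score is
scale-invariant (units cancel), lies in $[0,1]$, and exactly one
mutation attains 1 whenever any component is non-zero. Agreement with an
external per-mutation reference score is summarized by the sample
Pearson correlation over the shared mutation set
(`correlate_with_reference()`).

# Pipeline, problem sizes, and reproducibility

`run_pipeline()` chains the stages (ingest or synthesize → fit → WHAM →
impact → report), skipping stages whose inputs are absent and marking
the impact section incomplete rather than failing. The bundled
`synthetic_study()` cohort is one wild type plus four mutants of graded
severity ($\Delta T_m$ = 1, 3, 6, 10 K; $D_{1/2}$ shifts 0.1–0.8 M;
chemical hysteresis 0.30–0.60 M, 0.365 M for wild type; matching
replica-exchange $T_\mathrm{ref}$ shifts; three predictor tools tracking
severity; reference scores increasing with severity), so the expected
ordering and the top score of exactly 1 are known in advance.

Problem sizes used in the test-suite and acceptance runs — 15-condition
thermal scans, 17-condition titrations, 8 × 20,000-frame
replica-exchange datasets, 100-seed noise studies, 5-run averages for
the standard-error comparisons — were chosen so the whole validation
executes in a few minutes on one core while leaving every comparison
statistically meaningful.

Known limitations, beyond those noted above: no three-state or
sloped-baseline unfolding models; no MBAR generalization or bias
(umbrella) support in WHAM; no autocorrelation correction; the
Cv-peak-integral $\Delta H_m$ is an effective quantity that depends on
the half-maximum convention; exact reproduction of any particular
published bar heights is not claimed, since predictor aggregation and
the $m$-value entering the chemical route are configurable conventions.
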
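test_that("single-temperature WHAM reduces to the raw histogram", {
  d <- make_two_level_dataset(temps = 300, n_per_temp = 2000L, seed = 3L)
  wh <- wham_solve(d, bins = 10L)
  expect_true(wh$converged)
  # frame weights at the simulation temperature are exactly uniform
  w <- wham_frame_weights(d, wh, 300)
  expect_lt(max(abs(w - 1 / length(w))), 1e-12)
  # Omega(E_b) proportional to n_b * exp(beta E_b) on occupied bins
  E <- d$frames$energy_kcal_mol
  counts <- table(E)
  lnomega_direct <- log(as.numeric(counts)) +
    as.numeric(names(counts)) / (R_gas * 300)
  occ <- which(is.finite(wh$ln_omega))
  expect_equal(diff(wh$ln_omega[occ]), diff(lnomega_direct),
               tolerance = 1e-9)
})

test_that("WHAM recovers equal densities for a symmetric two-level system", {
  # both levels non-degenerate -> ln Omega difference should be zero
  diffs <- vapply(1:8, function(seed) {
    d <- make_two_level_dataset(dE = 1.5, n_per_temp = 3000L, seed = seed)
    wh <- wham_solve(d, bins = 2L)
    occ <- which(is.finite(wh$ln_omega))
    wh$ln_omega[occ[2]] - wh$ln_omega[occ[1]]
  }, numeric(1))
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("WHAM free energies are translation invariant", {
  d <- make_two_level_dataset(n_per_temp = 1500L, seed = 6L)
  wh <- wham_solve(d, bins = 5L)
  shift <- 7.3
  d2 <- d
  d2$frames$energy_kcal_mol <- d$frames$energy_kcal_mol + shift
  wh2 <- wham_solve(d2, bins = 5L)
  beta <- 1 / (R_gas * wh$temperatures)
  expect_equal(wh2$f_k - wh$f_k, shift * (beta - beta[1]), tolerance = 1e-6)
  # reweighted averages unchanged (up to the shift itself)
  for (temp in c(290, 310, 330)) {
    m1 <- reweight_observable(d, wh, "energy_kcal_mol", temp)$mean
    m2 <- reweight_observable(d2, wh2, "energy_kcal_mol", temp)$mean
    expect_equal(m2 - shift, m1, tolerance = 1e-8)
  }
})

test_that("heat capacity vanishes for a degenerate dataset", {
  frames <- data.frame(step = 1:50, replica_id = 1L, temperature_K = 300,
                       energy_kcal_mol = -5, rg_angstrom = 15,
                       helix_fraction = 0.5)
  wh <- wham_solve(rex_dataset(frames))
  cv <- compute_cv(wh, T_grid = seq(290, 310, by = 1))
  expect_true(all(cv$Cv == 0))
})

test_that("two-level heat capacity peaks where the closed form says", {
  # exact density of states: two non-degenerate levels at 0 and -1.5;
  # closed-form peak temperature solves u tanh(u/2) = 2, u = dE/(R T)
  dE <- 1.5
  wh <- make_exact_wham(energies = c(-dE, 0), ln_omega = c(0, 0))
  cv <- compute_cv(wh, T_grid = seq(280, 350, by = 0.5))
  u_star <- stats::uniroot(function(u) u * tanh(u / 2) - 2, c(1, 5),
                           tol = 1e-12)$root
  t_star <- dE / (R_gas * u_star)
  expect_equal(attr(cv, "Tm_K"), t_star, tolerance = 0.01)
  # closed-form Cv values on the grid
  u <- dE / (R_gas * cv$T_K)
  cv_exact <- dE^2 / (R_gas * cv$T_K^2) * exp(u) / (1 + exp(u))^2
  expect_equal(cv$Cv, cv_exact, tolerance = 1e-10)
})

test_that("Cv extrapolation beyond the ladder is refused", {
  d <- make_two_level_dataset(n_per_temp = 500L, seed = 1L)
  wh <- wham_solve(d, bins = 4L)
  expect_error(compute_cv(wh, T_grid = seq(100, 200, 10)), "extrapolation")
})

test_that("WHAM reweighting reproduces the Zimm-Bragg oracle", {
  cfg <- zimm_bragg_config(frames_per_replica = 5000L, seed = 13L)
  d <- simulate_rex_zimm_bragg(cfg)
  wh <- wham_solve(d)
  expect_true(wh$converged)
  # reweighted mean energy at each ladder temperature vs raw and analytic
  test_temps <- c(310, 335, 350, 370)
  re <- reweight_observable(d, wh, "energy_kcal_mol", test_temps)
  an <- zimm_bragg_analytic(cfg, test_temps)
  # single-seed check at the 0.5% level of the transition energy scale;
  # the across-seed standard-error comparison lives with the acceptance
  # checks, where several independent runs are averaged
  expect_lt(max(abs(re$mean - an$E_mean)), 3)
  # Cv-peak melting temperature against the analytic argmax
  cv <- compute_cv(wh)
  expect_lt(abs(attr(cv, "Tm_K") - analytic_cv_peak(cfg)), 3)
})

test_that("delta Tm uses the wild-type-minus-mutant sign convention", {
  wh <- make_exact_wham(energies = c(-1.5, 0), ln_omega = c(0, 0))
  cv_wt <- compute_cv(wh, T_grid = seq(280, 350, 0.5))
  wh_mut <- make_exact_wham(energies = c(-1.4, 0), ln_omega = c(0, 0))
  cv_mut <- compute_cv(wh_mut, T_grid = seq(280, 350, 0.5))
  dtm <- delta_tm(list(WT = cv_wt, mut = cv_mut))
  expect_equal(unname(dtm["WT"]), 0)
  expect_gt(dtm[["mut"]], 0)     # lower-melting mutant => positive shift
  wh_stab <- make_exact_wham(energies = c(-1.6, 0), ln_omega = c(0, 0))
  cv_stab <- compute_cv(wh_stab, T_grid = seq(280, 360, 0.5))
  expect_lt(delta_tm(list(WT = cv_wt, stab = cv_stab))[["stab"]], 0)
  expect_error(delta_tm(list(mut = cv_mut)), "missing")
})

test_that("PMF differences follow -RT ln P exactly", {
  # 9:1 population split at a single temperature: weights are uniform,
  # so the two-bin PMF difference is R * 300 * ln 9
  frames <- data.frame(step = 1:1000, replica_id = 1L, temperature_K = 300,
                       energy_kcal_mol = 0,
                       rg_angstrom = rep(c(12, 22), times = c(900, 100)),
                       helix_fraction = 0.5)
  d <- rex_dataset(frames)
  wh <- wham_solve(d, bins = 1L)
  pmf <- compute_pmf(d, wh, coords = "rg_angstrom", T_K = 300, bins = 2L)
  vals <- pmf$pmf[is.finite(pmf$pmf)]
  expect_equal(max(vals) - min(vals), R_gas * 300 * log(9), tolerance = 1e-9)
  expect_equal(min(pmf$pmf), 0)
  # the PMF minimum is the modal bin
  expect_equal(which.min(pmf$pmf), 1L)

  # uniform split -> flat landscape
  frames$rg_angstrom <- rep(c(12, 22), each = 500)
  d2 <- rex_dataset(frames)
  pmf2 <- compute_pmf(d2, wham_solve(d2, bins = 1L), coords = "rg_angstrom",
                      T_K = 300, bins = 2L)
  expect_equal(max(pmf2$pmf) - min(pmf2$pmf), 0, tolerance = 1e-12)
})

test_that("2D PMF basins are stable under bin refinement", {
  cfg <- zimm_bragg_config(frames_per_replica = 3000L, seed = 17L)
  d <- simulate_rex_zimm_bragg(cfg)
  wh <- wham_solve(d)
  basin_of <- function(bins) {
    pmf <- compute_pmf(d, wh, T_K = 305, bins = bins)
    idx <- arrayInd(which.min(pmf$pmf), dim(pmf$pmf))
    c(mean(pmf$edges[[1]][idx[1] + 0:1]), mean(pmf$edges[[2]][idx[2] + 0:1]))
  }
  b50 <- basin_of(50L)
  b100 <- basin_of(100L)
  width50 <- vapply(compute_pmf(d, wh, T_K = 305, bins = 50L)$edges,
                    function(e) diff(e)[1], numeric(1))
  expect_true(all(abs(b100 - b50) < width50))
})

test_that("Rg melt reproduces the transition midpoint", {
  cfg <- zimm_bragg_config(frames_per_replica = 12000L, seed = 19L)
  d <- simulate_rex_zimm_bragg(cfg)
  wh <- wham_solve(d)
  rg <- rg_melting_fit(d, wh)
  cv <- compute_cv(wh)
  expect_lt(abs(rg$midpoint_K - attr(cv, "Tm_K")), 3)
  expect_gt(rg$amplitude, 0)
  # reweighted <Rg>(T) increases on melting
  expect_true(all(diff(rg$curve$rg_mean) > -1e-6))
})

test_that("exchange summary counts acceptances per pair", {
  frames <- data.frame(step = rep(1:10, each = 2), replica_id = rep(1:2, 10),
                       temperature_K = rep(c(300, 320), 10),
                       energy_kcal_mol = 0, rg_angstrom = 15,
                       helix_fraction = 0.5)
  xlog <- data.frame(step = 1:10, replica_a = 1L, replica_b = 2L,
                     accepted = rep(c(TRUE, FALSE, FALSE), length.out = 10))
  # 1,4,7,10 accepted -> 4 of 10
  xlog$accepted <- seq_len(10) %% 3 == 1
  d <- rex_dataset(frames, xlog)
  rates <- exchange_rate_summary(d)
  expect_equal(nrow(rates), 1L)
  expect_equal(rates$attempts, 10L)
  expect_equal(rates$rate, 0.4)
  expect_error(exchange_rate_summary(rex_dataset(frames)), "empty exchange log")
})

test_that("non-convergence is flagged but returns a partial solution", {
  d <- make_two_level_dataset(n_per_temp = 500L, seed = 2L)
  expect_warning(wh <- wham_solve(d, bins = 4L, max_iter = 2L),
                 "did not converge")
  expect_false(wh$converged)
  expect_true(is.finite(wh$residual))
})
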
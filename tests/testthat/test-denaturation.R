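test_that("lambda-max extraction reaches sub-grid resolution", {
  wl <- seq(290, 360, by = 1)
  gauss <- function(center) exp(-0.5 * ((wl - center) / 12)^2)
  sp <- list(wavelength_nm = wl, intensity = gauss(330))
  expect_equal(as.numeric(extract_lambda_max(sp)), 330)

  # dense-grid argmax oracle for an off-grid peak
  sp2 <- list(wavelength_nm = wl, intensity = gauss(331.3))
  dense <- seq(290, 360, by = 0.001)
  oracle <- dense[which.max(exp(-0.5 * ((dense - 331.3) / 12)^2))]
  got <- extract_lambda_max(sp2)
  expect_lt(abs(as.numeric(got) - oracle), 0.05)
  expect_false(attr(got, "boundary"))

  sp3 <- list(wavelength_nm = wl, intensity = seq_along(wl))
  got3 <- extract_lambda_max(sp3)
  expect_equal(as.numeric(got3), 360)
  expect_true(attr(got3, "boundary"))

  sp4 <- list(wavelength_nm = wl, intensity = rep(1, length(wl)))
  expect_error(extract_lambda_max(sp4), "no unique maximum")
})

test_that("signal curves follow the generator's ground truth", {
  ser <- tiny_spectra_series(n_cond = 15L, noise_sd = 0)
  lam <- build_signal_curve(ser, "lambda_max")
  expect_true(all(diff(lam$y) >= -1e-9))        # monotone red shift
  expect_lt(abs(lam$y[1] - 330), 0.5)
  expect_gt(lam$y[15], 347)
  pk <- build_signal_curve(ser, "peak_intensity")
  # peak intensity decays while the native band dominates; past the band
  # crossover the maximum tracks the (weaker) unfolded band, so only a
  # net decrease is guaranteed, not point-wise monotonicity
  expect_true(all(diff(pk$y[pk$x <= 338]) < 0))
  expect_lt(pk$y[15], pk$y[1] - 25)

  small <- tiny_spectra_series(n_cond = 3L)
  expect_error(build_signal_curve(small, "lambda_max"), "at least 6")
})

test_that("model evaluations match hand-computed values and limits", {
  # midpoint identity, exact
  expect_identical(eval_thermal_model(50, 333, 100, -60, 333), 100 - 30)
  expect_identical(eval_chemical_model(4, 2, 330, 20, 298, 2), 330 + 10)
  # frozen direct evaluations
  expect_equal(eval_thermal_model(50, 333, 100, -60, 343), 45.96955,
               tolerance = 1e-6)
  expect_equal(eval_chemical_model(4, 2, 330, 20, 298, 1), 330.6602,
               tolerance = 1e-6)
  # step-function and fully-folded limits
  expect_lt(abs(eval_thermal_model(1e5, 333, 100, -60, 332) - 100), 1e-6 * 60)
  expect_lt(abs(eval_chemical_model(10, 2, 330, 20, 298, 0) - 330), 1e-6 * 20)
})

test_that("thermal model is monotone in temperature", {
  withr::with_seed(21L, {
    for (i in 1:20) {
      dH <- runif(1, 20, 120)
      Tm <- runif(1, 310, 350)
      Yd <- sample(c(-1, 1), 1) * runif(1, 10, 80)
      x <- seq(280, 380, by = 2)
      y <- eval_thermal_model(dH, Tm, 100, Yd, x)
      # monotone in the direction of Yd (saturated tails may be flat to
      # machine precision)
      expect_true(all(sign(diff(y)) * sign(Yd) >= 0))
    }
  })
})

test_that("fits recover noise-free ground truth across random draws", {
  withr::with_seed(31L, {
    for (i in 1:10) {
      dH <- runif(1, 30, 90); Tm <- runif(1, 315, 345)
      Yn <- runif(1, 50, 150); Yd <- sample(c(-1, 1), 1) * runif(1, 20, 60)
      fit <- fit_thermal(make_thermal_curve(dH, Tm, Yn, Yd))
      expect_true(fit$converged)
      expect_equal(fit$Tm_K, Tm, tolerance = 1e-4)
      expect_equal(fit$dH_app, dH, tolerance = 1e-4)
      expect_equal(fit$Yn, Yn, tolerance = 1e-4)
      expect_equal(fit$Yd, Yd, tolerance = 1e-4)

      dG <- runif(1, 2, 6); m <- runif(1, 1.5, 3)
      fitc <- fit_chemical(make_chemical_curve(dG, m, Yn, Yd))
      expect_equal(fitc$dG_app, dG, tolerance = 1e-4)
      expect_equal(fitc$m_value, m, tolerance = 1e-4)
      expect_equal(fitc$D_half, dG / m, tolerance = 1e-4)
    }
  })
})

test_that("fitted midpoint sits exactly at half the transition amplitude", {
  fit <- fit_thermal(make_thermal_curve(noise_sd = 0.5, seed = 2L))
  expect_equal(eval_thermal_model(fit$dH_app, fit$Tm_K, fit$Yn, fit$Yd,
                                  fit$Tm_K),
               fit$Yn + fit$Yd / 2, tolerance = 1e-12)
  fitc <- fit_chemical(make_chemical_curve(noise_sd = 0.2, seed = 2L))
  expect_equal(eval_chemical_model(fitc$dG_app, fitc$m_value, fitc$Yn,
                                   fitc$Yd, fitc$T_K, fitc$D_half),
               fitc$Yn + fitc$Yd / 2, tolerance = 1e-12)
})

test_that("fits are invariant to affine rescaling of the signal", {
  curve <- make_thermal_curve(noise_sd = 0.5, seed = 8L)
  scaled <- curve
  scaled$y <- 3.7 * curve$y + 41
  f1 <- fit_thermal(curve)
  f2 <- fit_thermal(scaled)
  expect_equal(f2$Tm_K, f1$Tm_K, tolerance = 1e-6)
  expect_equal(f2$dH_app, f1$dH_app, tolerance = 1e-6)
  expect_equal(f2$Yn, 3.7 * f1$Yn + 41, tolerance = 1e-5)
  expect_equal(f2$Yd, 3.7 * f1$Yd, tolerance = 1e-5)
})

test_that("flat curves are rejected as degenerate transitions", {
  x <- seq(293, 363, by = 5)
  flat <- signal_curve(x, rep(100, length(x)) +
                         withr::with_seed(1L, rnorm(length(x), sd = 0.01)),
                       "peak_intensity", "temperature", "unfolding")
  expect_error(fit_thermal(flat), "degenerate transition")
  flatc <- signal_curve(seq(0, 4, length.out = 15), rep(330, 15),
                        "lambda_max", "denaturant", "unfolding")
  expect_error(fit_chemical(flatc), "degenerate transition")
})

test_that("normalization maps the fit baseline to fraction unfolded", {
  curve <- make_thermal_curve()
  fit <- fit_thermal(curve)
  norm <- normalize_signal_curve(curve, fit)
  expect_true(norm$normalized)
  expect_true(all(norm$y >= -0.1 & norm$y <= 1.1))
  i_mid <- which.min(abs(curve$x - fit$Tm_K))
  expect_lt(abs(norm$y[i_mid] - 0.5), 0.05)
})

test_that("stability deltas follow the wild-type-minus-mutant convention", {
  wtf <- fit_thermal(make_thermal_curve(Tm_K = 333))
  mutf <- fit_thermal(make_thermal_curve(Tm_K = 323))
  wt_ch <- list(unfolding = fit_chemical(make_chemical_curve(4, 2)),
                refolding = fit_chemical(make_chemical_curve(3.27, 2)))
  mut_ch <- list(unfolding = fit_chemical(make_chemical_curve(2.4, 2)),
                 refolding = fit_chemical(make_chemical_curve(1.2, 2)))
  d <- stability_deltas(thermal = list(WT = wtf, mut = mutf),
                        chemical = list(WT = wt_ch, mut = mut_ch))
  wt_row <- d[d$variant == "WT", ]
  mut_row <- d[d$variant == "mut", ]
  expect_equal(wt_row$delta_Tm, 0)
  expect_equal(wt_row$delta_delta_D_half, 0)
  expect_equal(mut_row$delta_Tm, 10, tolerance = 1e-3)
  # hysteresis: WT 2 - 1.635 = 0.365; mut 1.2 - 0.6 = 0.6
  expect_equal(wt_row$delta_D_half, 0.365, tolerance = 1e-3)
  expect_equal(mut_row$delta_delta_D_half, 0.365 - 0.6, tolerance = 1e-3)
  expect_equal(mut_row$delta_D_half_unf_vs_wt, 2 - 1.2, tolerance = 1e-3)

  expect_error(stability_deltas(thermal = list(mut = mutf)), "missing")
})
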
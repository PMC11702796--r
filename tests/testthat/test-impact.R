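test_that("melting-shift conversion is the van't Hoff first-order formula", {
  expect_equal(ddg_from_tm_shift(50, 0, 333), 0)
  expect_equal(ddg_from_tm_shift(50, 10, 333), 1.502, tolerance = 1e-3)
  expect_equal(ddg_from_tm_shift(50, -5, 333), -50 * 5 / 333)
  # linearity at random points
  withr::with_seed(5L, {
    for (i in 1:5) {
      dtm <- runif(1, -20, 20)
      expect_equal(ddg_from_tm_shift(50, 2 * dtm, 333),
                   2 * ddg_from_tm_shift(50, dtm, 333))
    }
  })
  expect_error(ddg_from_tm_shift(-1, 5, 333), "dHm")
  expect_error(ddg_from_tm_shift(50, 5, 0), "Tm_K")
})

test_that("chemical conversion multiplies the m-value by the midpoint shift", {
  expect_equal(ddg_from_chemical(2, 0), 0)
  expect_equal(ddg_from_chemical(2, 0.365), 0.730)
  expect_equal(ddg_from_chemical(2, -0.365), -0.730)
  withr::with_seed(6L, {
    dd <- runif(5, -1, 1)
    expect_equal(ddg_from_chemical(2, 2 * dd), 2 * ddg_from_chemical(2, dd))
  })
  expect_error(ddg_from_chemical(0, 1), "m_value")
})

test_that("Cv-peak enthalpy integrates the exact two-level peak", {
  # the two-level Cv peak is broad: the high side falls to half maximum
  # only near 1200 K, so the grid and oracle brackets span that range
  dE <- 1.5
  wh <- make_exact_wham(energies = c(-dE, 0), ln_omega = c(0, 0),
                        temperatures = c(50, 2000))
  cv <- compute_cv(wh, T_grid = seq(75, 1500, by = 0.5))
  got <- cv_peak_enthalpy(cv)
  # independent oracle: integrate the closed-form Cv above its half
  # maximum between the half-maximum crossings found by root bracketing
  cv_exact <- function(temp) {
    u <- dE / (R_gas * temp)
    dE^2 / (R_gas * temp^2) * exp(u) / (1 + exp(u))^2
  }
  t_pk <- stats::optimize(function(x) -cv_exact(x), c(100, 600))$minimum
  half <- cv_exact(t_pk) / 2
  t1 <- stats::uniroot(function(x) cv_exact(x) - half, c(75, t_pk))$root
  t2 <- stats::uniroot(function(x) cv_exact(x) - half, c(t_pk, 1500))$root
  want <- stats::integrate(function(x) cv_exact(x) - half, t1, t2)$value
  expect_equal(got, want, tolerance = 0.01)
})

test_that("predictor aggregation follows the configured rule", {
  tab <- predictor_table(data.frame(
    mutation = rep(c("mA", "mB"), each = 3),
    tool = rep(c("t1", "t2", "t3"), 2),
    ddg_kcal_mol = c(-1, -2, -3, -1, -2, 0.5)))
  expect_equal(aggregate_predictor_ddg(tab, "mean")[["mA"]], -2)
  expect_equal(aggregate_predictor_ddg(tab, "median")[["mB"]], -1)
  one <- predictor_table(data.frame(mutation = "mA", tool = "t1",
                                    ddg_kcal_mol = -1.7))
  expect_equal(aggregate_predictor_ddg(one, "mean")[["mA"]], -1.7)
  expect_equal(aggregate_predictor_ddg(tab, "tool", tool = "t2")[["mA"]], -2)
  tab2 <- predictor_table(data.frame(mutation = c("mA", "mA", "mB"),
                                     tool = c("t1", "t2", "t1"),
                                     ddg_kcal_mol = c(-1, -2, -3)))
  expect_error(aggregate_predictor_ddg(tab2, "tool", tool = "t2"), "absent")
})

test_that("overall impact normalizes by the largest component sum", {
  comp <- data.frame(mutation = c("A", "B"),
                     ddg_pt = c(1.0, 0.5), ddg_rex = c(0.5, 0.25),
                     ddg_td = c(1.0, 0.5), ddg_cd = c(0.5, 0.25))
  imp <- overall_impact(comp)
  expect_equal(imp$overall_impact, c(1.0, 0.5))
  expect_equal(attr(imp, "scaling_factor"), 3.0)

  solo <- overall_impact(comp[1, ])
  expect_equal(solo$overall_impact, 1.0)

  zero <- comp
  zero[, -1] <- 0
  expect_error(overall_impact(zero), "zero scaling factor")

  nas <- comp
  nas$ddg_cd[2] <- NA
  expect_error(overall_impact(nas), "allow_partial")
  imp2 <- overall_impact(nas, allow_partial = TRUE)
  expect_equal(imp2$n_components, c(4, 3))
})

test_that("impact score is scale invariant with maximum one", {
  withr::with_seed(41L, {
    comp <- data.frame(mutation = paste0("m", 1:6),
                       ddg_pt = rnorm(6), ddg_rex = rnorm(6),
                       ddg_td = rnorm(6), ddg_cd = rnorm(6))
    imp <- overall_impact(comp)
    expect_equal(max(imp$overall_impact), 1)
    scaled <- comp
    scaled[, -1] <- scaled[, -1] * 37.2
    expect_equal(overall_impact(scaled)$overall_impact, imp$overall_impact,
                 tolerance = 1e-12)
    # ranking invariant under row permutation
    perm <- sample(6)
    imp_p <- overall_impact(comp[perm, ])
    expect_equal(imp_p$overall_impact[order(imp_p$mutation)],
                 imp$overall_impact[order(imp$mutation)])
  })
})

test_that("reference correlation matches the covariance formula", {
  impacts <- c(m1 = 1.0, m2 = 0.5, m3 = 0.2)
  reference <- c(m1 = 0.9, m2 = 0.6, m3 = 0.1)
  got <- correlate_with_reference(impacts, reference)
  # textbook Pearson, written out independently
  a <- impacts - mean(impacts)
  b <- reference - mean(reference)
  want <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_equal(got$r, unname(want), tolerance = 1e-12)
  expect_equal(got$n_shared, 3L)

  expect_equal(correlate_with_reference(impacts, impacts)$r, 1)
  expect_equal(correlate_with_reference(impacts, -impacts)$r, -1)
  expect_error(correlate_with_reference(impacts[1:2], reference), "fewer than 3")
  expect_error(correlate_with_reference(impacts, c(m1 = 1, m2 = 1, m3 = 1)),
               "zero variance")
})
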
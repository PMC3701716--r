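test_that("the unfolded fraction respects its limits and the Tm anchor", {
  set.seed(7)
  for (i in 1:10) {
    dH <- runif(1, 40, 200)
    Tm <- runif(1, 300, 330)
    dCp <- runif(1, 0, 3)
    Ct <- 10^runif(1, -7, -4)
    ## exactly 1/2 at the melting temperature, whatever the parameters
    expect_equal(frac_unfolded(Tm, dH, Tm, dCp, Ct = Ct), 0.5,
                 tolerance = 1e-12)
    ## strictly increasing around Tm for a positive unfolding enthalpy
    f <- frac_unfolded(Tm + c(-1, 0, 1), dH, Tm, dCp, Ct = Ct)
    expect_true(all(diff(f) > 0))
    expect_true(all(f > 0 & f < 1))
  }
  ## extreme-stability limits
  expect_lt(frac_unfolded(280, 300, 330, 0, Ct = 4.2e-6), 1e-10)
  expect_gt(frac_unfolded(360, 300, 320, 0, Ct = 4.2e-6), 1 - 1e-6)
})

test_that("the closed-form dimer fraction matches a brute-force equilibrium solve", {
  for (T in seq(290, 340, by = 5)) {
    expect_equal(frac_unfolded(T, 100, 316, 1, Ct = 4.2e-6),
                 oracle_dimer_fraction(T, 100, 316, 1, Ct = 4.2e-6),
                 tolerance = 1e-9)
  }
  ## and with the equilibrium evaluated away from the anchoring concentration
  expect_equal(frac_unfolded(318, 100, 316, 1, Ct = 1e-4, Ct_ref = 4.2e-6),
               oracle_dimer_fraction(318, 100, 316, 1, Ct = 1e-4,
                                     Ct_ref = 4.2e-6),
               tolerance = 1e-9)
})

test_that("dG_unfold falls with slope -dH/Tm just above Tm when dCp = 0", {
  dH <- 120; Tm <- 316; Ct <- 4.2e-6
  eps <- 1e-4
  slope <- (dG_unfold(Tm + eps, dH, Tm, 0, Ct) -
              dG_unfold(Tm, dH, Tm, 0, Ct)) / eps
  ## Gibbs-Helmholtz slope plus the small concentration-term derivative
  expect_equal(slope, -dH / Tm - R_KCAL * log(Ct), tolerance = 1e-4)
  expect_error(dG_unfold(-1, dH, Tm, 0, Ct), "positive")
})

test_that("the intensity model is the baseline mixture of the two states", {
  ## flat baselines at Tm give the midpoint exactly
  expect_equal(intensity_model(316, 100, 316, 1, alpha_F = 80, beta_F = 0,
                               alpha_U = 20, beta_U = 0), 50,
               tolerance = 1e-9)
  ## deep in the folded regime the folded baseline is recovered
  expect_equal(intensity_model(287, 300, 330, 0, alpha_F = 80, beta_F = -0.1,
                               alpha_U = 20, beta_U = 0),
               80 - 0.1 * 287, tolerance = 1e-6)
})

test_that("intensity scaling fixes the maximum at 100", {
  cu <- melt_curve(seq(290, 325, 5), c(50, 45, 40, 30, 25, 10, 5, 2),
                   intensity_errors = rep(2, 8))
  sc <- scale_to_100(cu)
  expect_equal(max(sc$intensities), 100)
  expect_equal(sc$intensities[1:2], c(100, 90))
  expect_equal(sc$intensity_errors, rep(4, 8))
  expect_identical(scale_to_100(sc)$intensities, sc$intensities)
  cu$intensities <- -cu$intensities
  expect_error(scale_to_100(cu), "positive")
})

test_that("fitting a noiseless curve recovers the generating parameters", {
  spec <- melt_spec(dH = 110, Tm = 318, dCp = 1.2, alpha_F = 100,
                    alpha_U = 12, noise_sd = 0)
  curve <- gen_melt_curve(spec)
  fit <- fit_melt(curve, n_params = 5, scale = FALSE, multistart = 1)
  expect_true(fit$converged)
  expect_equal(fit$Tm, 318, tolerance = 1e-6)
  expect_equal(fit$dH, 110, tolerance = 1e-6)
  expect_equal(fit$dCp, 1.2, tolerance = 1e-5)
  expect_equal(fit$alpha_F, 100, tolerance = 1e-6)
  expect_equal(fit$alpha_U, 12, tolerance = 1e-6)
  ## the five-parameter model pins both baseline slopes at zero
  expect_identical(fit$beta_F, 0)
  expect_identical(fit$beta_U, 0)
  ## seven-parameter fit of a sloped-baseline truth
  spec7 <- melt_spec(dH = 110, Tm = 318, dCp = 1.2, alpha_F = 130,
                     beta_F = -0.1, alpha_U = 12, beta_U = 0.02,
                     noise_sd = 0)
  fit7 <- fit_melt(gen_melt_curve(spec7), n_params = 7, scale = FALSE,
                   multistart = 3, seed = 1)
  expect_equal(fit7$Tm, 318, tolerance = 1e-5)
  expect_equal(fit7$beta_F, -0.1, tolerance = 1e-4)
})

test_that("pre-scaling the curve does not move the fitted Tm", {
  curve <- gen_melt_curve(melt_spec(noise_sd = 0.5, seed = 21))
  fit_auto <- fit_melt(curve, 5, scale = TRUE, multistart = 1)
  fit_pre <- fit_melt(scale_to_100(curve), 5, scale = FALSE, multistart = 1)
  expect_equal(fit_auto$Tm, fit_pre$Tm, tolerance = 1e-6)
})

test_that("the nested-model F-test follows the residual chi-square arithmetic", {
  ft <- f_statistic(17.9, 14.7, 19)
  expect_equal(ft$F, ((17.9 - 14.7) / 2) / (14.7 / 12), tolerance = 1e-12)
  expect_equal(ft$df_num, 2)
  expect_equal(ft$df_den, 12)
  expect_equal(ft$F_critical, qf(0.95, 2, 12), tolerance = 1e-12)
  expect_false(ft$prefer_complex)

  ## equal fits: F = 0, simple model preferred
  ft0 <- f_statistic(10, 10, 19)
  expect_equal(ft0$F, 0)
  expect_false(ft0$prefer_complex)
  ## an inverted pair floors at zero with a warning
  expect_warning(ftw <- f_statistic(9, 10, 19), "floored")
  expect_equal(ftw$F, 0)

  curve <- gen_melt_curve(melt_spec(seed = 31))
  f5 <- fit_melt(curve, 5, multistart = 1)
  f7 <- fit_melt(curve, 7, multistart = 1,
                 start = list(dH = f5$dH, Tm = f5$Tm, dCp = f5$dCp,
                              alpha_F = f5$alpha_F, alpha_U = f5$alpha_U,
                              beta_F = 0, beta_U = 0))
  ft2 <- f_test(f5, f7)
  expect_gte(ft2$F, 0)
  expect_equal(ft2$df_den, 19 - 7)
  expect_error(f_test(f7, f5), "fewer parameters")
})

test_that("Monte-Carlo errors behave like errors", {
  curve <- gen_melt_curve(melt_spec(noise_sd = 0, seed = 41))
  fit <- fit_melt(curve, 5, scale = FALSE, multistart = 1)
  ## zero injected noise: every refit reproduces the fit exactly
  mc0 <- mc_errors(fit, noise_sd = 0, n_sets = 10, seed = 1)
  expect_equal(mc0$Tm, 0, tolerance = 1e-8)
  expect_equal(mc0$dH, 0, tolerance = 1e-6)
  expect_equal(mc0$dG_at_T_ref, 0, tolerance = 1e-8)

  ## errors grow about linearly with the injected noise at small noise
  mc1 <- mc_errors(fit, noise_sd = 0.5, n_sets = 60, seed = 2)
  mc2 <- mc_errors(fit, noise_sd = 1.0, n_sets = 60, seed = 2)
  expect_gt(mc2$Tm / mc1$Tm, 1.3)
  expect_lt(mc2$Tm / mc1$Tm, 3)

  ## enthalpy/heat-capacity compensation: the derived dG error is much
  ## smaller than the dH error (in relative terms)
  expect_lt(mc2$dG_at_T_ref / mc2$dH, 1)
})

test_that("experimental ddG has the stability sign convention", {
  wt <- fit_melt(gen_melt_curve(melt_spec(Tm = 316, noise_sd = 0)),
                 5, scale = FALSE, multistart = 1)
  mut <- fit_melt(gen_melt_curve(melt_spec(Tm = 326, noise_sd = 0)),
                  5, scale = FALSE, multistart = 1)
  expect_equal(ddG_experimental(wt, wt), 0, tolerance = 1e-10)
  d <- ddG_experimental(wt, mut)
  expect_lt(d, 0)  # higher-Tm variant is more stable -> negative ddG
  expect_equal(ddG_experimental(mut, wt, T_ref = 316), -ddG_experimental(wt, mut, T_ref = 316),
               tolerance = 1e-10)
  expect_warning(ddG_experimental(wt, mut, T_ref = 500), "outside")
})

test_that("melt-curve containers validate their inputs", {
  expect_error(melt_curve(1:5, 1:5), "at least 8")
  expect_error(melt_curve(c(1:7, 7), 1:8 * 1.0), "increasing")
  expect_error(melt_curve(1:8, 1:8, Ct = -1), "Ct")
  expect_error(melt_curve(1:8, 1:8, intensity_errors = rep(0, 8)),
               "positive")
  expect_error(fit_melt(gen_melt_curve(melt_spec()), n_params = 6), "5 or 7")
})
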
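test_that("zero-spread window generation is degenerate at the pair mean", {
  spec <- alchemy_spec(n_windows = 5, pair_mean = 1.5, pair_sd = 0,
                       samples_per_window = 20, seed = 1)
  w <- gen_alchemy_windows(spec)
  for (p in w) {
    expect_equal(p$forward, rep(1.5, 20))
    expect_equal(p$reverse, rep(1.5, 20))
  }
  expect_equal(attr(w, "truth")$dG_true, rep(1.5, 4))
})

test_that("a 21-window Coulomb-switching schedule yields 20 window pairs", {
  spec <- alchemy_spec(lambda_schedule = 0.05 * (0:20), pair_sd = 0.3,
                       samples_per_window = 10, seed = 2)
  w <- gen_alchemy_windows(spec)
  expect_length(w, 20)
  expect_equal(vapply(w, `[[`, numeric(1), "lambda_low"), 0.05 * (0:19))
  expect_equal(vapply(w, `[[`, numeric(1), "lambda_high"), 0.05 * (1:20))
  ## the finer van der Waals schedule
  w41 <- gen_alchemy_windows(alchemy_spec(
    lambda_schedule = 0.025 * (0:40), pair_sd = 0.3,
    samples_per_window = 10, seed = 2))
  expect_length(w41, 40)
})

test_that("Gaussian pair ground truth matches Zwanzig quadrature", {
  beta <- 1 / (R_KCAL * 300)
  ## mu = 2, sigma^2 = 2/beta gives dG = 1 kcal/mol in closed form
  spec <- alchemy_spec(n_windows = 2, pair_mean = 2, pair_sd = sqrt(2 / beta),
                       samples_per_window = 10, temperature = 300, seed = 3)
  truth <- attr(gen_alchemy_windows(spec), "truth")$dG_true
  expect_equal(truth, 1.0, tolerance = 1e-12)
  expect_equal(truth, oracle_gaussian_zwanzig(2, sqrt(2 / beta), 300),
               tolerance = 1e-8)
  ## and for an asymmetric case
  spec2 <- alchemy_spec(n_windows = 2, pair_mean = -0.7, pair_sd = 0.9,
                        samples_per_window = 10, temperature = 310, seed = 3)
  expect_equal(attr(gen_alchemy_windows(spec2), "truth")$dG_true,
               oracle_gaussian_zwanzig(-0.7, 0.9, 310), tolerance = 1e-8)
})

test_that("generators are byte-identical under a fixed seed", {
  a1 <- gen_alchemy_windows(alchemy_spec(n_windows = 4, seed = 11))
  a2 <- gen_alchemy_windows(alchemy_spec(n_windows = 4, seed = 11))
  a3 <- gen_alchemy_windows(alchemy_spec(n_windows = 4, seed = 12))
  expect_identical(a1, a2)
  expect_false(identical(a1[[1]]$forward, a3[[1]]$forward))

  m1 <- gen_melt_curve(melt_spec(seed = 11))
  m2 <- gen_melt_curve(melt_spec(seed = 11))
  expect_identical(m1, m2)

  s1 <- gen_alignment(alignment_spec(n_sequences = 10, length = 6, seed = 11))
  s2 <- gen_alignment(alignment_spec(n_sequences = 10, length = 6, seed = 11))
  expect_identical(s1, s2)
})

test_that("invalid generator specs are rejected", {
  expect_error(alchemy_spec(lambda_schedule = c(0, 0.5, 0.4, 1)),
               "increasing")
  expect_error(alchemy_spec(lambda_schedule = c(0.1, 0.5, 1)), "start at 0")
  expect_error(alchemy_spec(pair_sd = -1), "pair_sd")
  expect_error(alchemy_spec(samples_per_window = 1), "samples_per_window")
  expect_error(melt_spec(Tm = 400), "within the temperature grid")
  expect_error(melt_spec(Ct = 0), "Ct")
  expect_error(alignment_spec(n_sequences = 5,
                              column_compositions = list(c(A = 3))), "sum")
})

test_that("noiseless melt curves satisfy the two-state model identically", {
  grid <- seq(286, 346, by = 3)  # contains Tm = 316 exactly
  spec <- melt_spec(dH = 120, Tm = 316, dCp = 1.5, alpha_F = 95,
                    alpha_U = 12, beta_F = -0.05, beta_U = 0.01,
                    temperatures = grid, noise_sd = 0, seed = 5)
  curve <- gen_melt_curve(spec)
  expect_equal(curve$intensities,
               intensity_model(grid, 120, 316, 1.5, 95, -0.05, 12, 0.01,
                               Ct = spec$Ct),
               tolerance = 1e-12)
  ## at Tm the unfolded fraction is exactly 1/2, so the intensity is the
  ## midpoint of the two baselines
  i_tm <- curve$intensities[grid == 316]
  expect_equal(i_tm, ((95 - 0.05 * 316) + (12 + 0.01 * 316)) / 2,
               tolerance = 1e-10)
  ## the measurement concentration used throughout is 4.2 uM monomer
  expect_equal(spec$Ct, 4.2e-6)
})

test_that("raising Ct above the reference concentration raises the half-transition", {
  lo <- melt_spec(noise_sd = 0, Ct = 4.2e-6, Ct_ref = 4.2e-6)
  hi <- melt_spec(noise_sd = 0, Ct = 4.2e-4, Ct_ref = 4.2e-6)
  t_lo <- oracle_half_transition(lo$dH, lo$Tm, lo$dCp, lo$Ct, lo$Ct_ref)
  t_hi <- oracle_half_transition(hi$dH, hi$Tm, hi$dCp, hi$Ct, hi$Ct_ref)
  expect_equal(t_lo, lo$Tm, tolerance = 1e-6)
  expect_gt(t_hi, t_lo + 0.5)
  ## the generated curves reflect the shift: at Tm the higher-concentration
  ## sample is still mostly folded
  expect_lt(frac_unfolded(hi$Tm, hi$dH, hi$Tm, hi$dCp,
                          Ct = hi$Ct, Ct_ref = hi$Ct_ref), 0.5)
})

test_that("alignment generation honours exact per-column compositions", {
  comps <- list(c(V = 83), c(V = 65, I = 13, L = 5), c(A = 40, `-` = 43))
  spec <- alignment_spec(n_sequences = 83, column_compositions = comps,
                         seed = 7)
  seqs <- gen_alignment(spec)
  expect_length(seqs, 83)
  mat <- do.call(rbind, strsplit(seqs, ""))
  expect_true(all(mat[, 1] == "V"))
  expect_equal(sum(mat[, 2] == "V"), 65)
  expect_equal(sum(mat[, 2] == "I"), 13)
  expect_equal(sum(mat[, 2] == "L"), 5)
  expect_equal(sum(mat[, 3] == "-"), 43)
})

test_that("window pairs and alignments round-trip through their file formats", {
  spec <- alchemy_spec(n_windows = 3, samples_per_window = 25, seed = 9)
  w <- gen_alchemy_windows(spec)
  dir <- withr::local_tempdir()
  write_window_pairs(w, dir)
  w2 <- read_window_pairs(dir, temperature = spec$temperature)
  expect_length(w2, 2)
  for (i in 1:2) {
    expect_equal(w2[[i]]$forward, w[[i]]$forward, tolerance = 1e-12)
    expect_equal(w2[[i]]$reverse, w[[i]]$reverse, tolerance = 1e-12)
    expect_equal(w2[[i]]$lambda_low, w[[i]]$lambda_low)
  }

  seqs <- gen_alignment(alignment_spec(n_sequences = 6, length = 8, seed = 9))
  fa <- file.path(dir, "aln.fasta")
  write_alignment_fasta(seqs, fa)
  expect_identical(read_alignment_fasta(fa), seqs)

  curve <- gen_melt_curve(melt_spec(seed = 9))
  csv <- file.path(dir, "melt.csv")
  write_melt_csv(curve, csv)
  curve2 <- read_melt_csv(csv)
  expect_equal(curve2$intensities, curve$intensities, tolerance = 1e-12)
  ## Celsius round trip
  write_melt_csv(curve, csv, celsius = TRUE)
  curve3 <- read_melt_csv(csv, celsius = TRUE)
  expect_equal(curve3$temperatures, curve$temperatures, tolerance = 1e-9)
})
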
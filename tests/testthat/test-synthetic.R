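test_that("reference spectra have the expected band maxima and separations", {
  refs <- make_reference_spectra("flavin_LOV")
  grid <- refs$analyte_ox$wavelengths
  argmax <- function(s) grid[which.max(s$values)]
  expect_gte(argmax(refs$analyte_ox), 440)
  expect_lte(argmax(refs$analyte_ox), 455)
  expect_gte(argmax(refs$indicator_ox), 510)
  expect_lte(argmax(refs$indicator_ox), 530)
  # hydroquinone is essentially transparent at the quinone maximum
  at450 <- function(s) spectrum_at(s, 450)
  expect_lt(at450(refs$analyte_red), 0.1 * at450(refs$analyte_ox))

  ribo <- make_reference_spectra("riboflavin")
  expect_gte(argmax(ribo$analyte_ox), 440)
  expect_lte(argmax(ribo$analyte_ox), 455)

  pair <- make_reference_spectra("phenosafranine_pair")
  expect_named(pair, c("ox", "red"))
  expect_error(make_reference_spectra("flavin_LOV", grid = 400:500),
               "cover", class = "lov_validation_error")
})

test_that("potential trajectory is the stated exponential relaxation", {
  p <- titration_sim_params(E_start_mv = -100, E_end_mv = -400,
                            tau_s = 3600)
  expect_equal(potential_trajectory(p, 0), -100)
  expect_equal(potential_trajectory(p, 1e9), -400)
  # closed form at one time constant: -400 + 300/e
  expect_equal(potential_trajectory(p, 3600), -400 + 300 * exp(-1),
               tolerance = 1e-12)
  expect_equal(round(potential_trajectory(p, 3600), 1), -289.6)
  expect_true(all(diff(potential_trajectory(p, seq(0, 1e4, 100))) < 0))
  expect_error(titration_sim_params(tau_s = -1), "tau",
               class = "lov_validation_error")
  expect_error(titration_sim_params(E_start_mv = -400, E_end_mv = -100),
               "below", class = "lov_validation_error")
})

test_that("titration truth follows Nernst equilibria and is seeded", {
  refs <- make_reference_spectra("flavin_LOV")
  # potential pinned (numerically) at the indicator midpoint
  pinned <- titration_sim_params(
    E_start_mv = -252 + 1e-9, E_end_mv = -252 - 1e-9, tau_s = 1e9,
    noise_sd = 0, duration_s = 1000, n_timepoints = 10)
  sim <- simulate_titration(pinned, refs)
  expect_equal(sim$truth$indicator$f_red, rep(0.5, 10), tolerance = 1e-9)

  # complete reduction at potentials far below both midpoints
  deep <- titration_sim_params(E_end_mv = -500, tau_s = 2000,
                               duration_s = 40000, noise_sd = 0)
  simd <- simulate_titration(deep, refs)
  expect_gt(tail(simd$truth$analyte$f_red, 1), 0.999)

  # fractions sum to one exactly
  expect_equal(sim$truth$analyte$f_ox + sim$truth$analyte$f_red,
               rep(1, 10))

  # determinism: same seed bitwise identical, different seed differs only
  # in the noise realization
  p <- titration_sim_params(seed = 11)
  a <- simulate_titration(p, refs)
  b <- simulate_titration(p, refs)
  expect_identical(as_matrix(a$series), as_matrix(b$series))
  p2 <- titration_sim_params(seed = 12)
  c2 <- simulate_titration(p2, refs)
  expect_false(identical(as_matrix(a$series), as_matrix(c2$series)))
  expect_identical(a$truth$analyte$f_red, c2$truth$analyte$f_red)
})

test_that("exponential traces obey half-life, rate-sum, and plateau identities", {
  k <- 0.013
  tr <- simulate_exponential_trace("recovery", k, times = seq(0, 400, 0.1),
                                   noise_sd = 0)
  t_half <- log(2) / k
  halfway <- (min(tr$signal) + 0.45) / 2  # start and plateau midpoint
  expect_equal(spline_at <- approx(tr$times, tr$signal, t_half)$y,
               0.45 - 0.40 / 2, tolerance = 1e-6)

  pa <- simulate_exponential_trace("photoactivation", c(0.048, 0.013),
                                   times = seq(0, 300, 1), noise_sd = 0)
  # observed decay rate is the sum of the microscopic rates
  fit <- fit_photoactivation(pa, k_rec = 0.013)
  expect_equal(fit$rate_observed, 0.061, tolerance = 1e-6)
  # photostationary plateau: dark fraction k_rec / (k1 + k_rec)
  expect_equal(min(pa$signal) / 0.45, 0.013 / 0.061, tolerance = 1e-3)
  expect_equal(0.013 / 0.061, 0.2131, tolerance = 1e-4)
  expect_error(simulate_exponential_trace("recovery", -0.1),
               class = "lov_validation_error")
})

test_that("Arrhenius simulator matches the closed form and refits exactly", {
  s <- simulate_arrhenius_series(61, 0.013, temperatures = c(295.15, 311.15))
  expect_equal(s$k[1], 0.013)
  expect_equal(s$k[2], 0.0467, tolerance = 1e-3)
  flat <- simulate_arrhenius_series(0, 0.013)
  expect_true(all(flat$k == 0.013))
  # noiseless series refit by fit_arrhenius returns EA to machine precision
  ser <- simulate_arrhenius_series(61, 0.013)
  expect_equal(fit_arrhenius(ser)$EA_kj_mol, 61, tolerance = 1e-9)
  expect_error(simulate_arrhenius_series(61, 0.013, temperatures = 350),
               "280-320", class = "lov_validation_error")
})

test_that("dilution-series simulator encodes the slope-ratio identity", {
  eq <- simulate_dilution_series(0.54, phi_ref = 0.54, n_sample = 1.36,
                                 n_ref = 1.36, noise_cv = 0)
  ms <- fit_dilution_slope(eq$sample)$slope
  mr <- fit_dilution_slope(eq$reference)$slope
  expect_equal(ms, mr, tolerance = 1e-12)

  # noiseless slopes are exact and invert to phi_true through the
  # slope-ratio relation
  ds <- simulate_dilution_series(0.09, noise_cv = 0)
  mF <- fit_dilution_slope(ds$sample)$slope
  mR <- fit_dilution_slope(ds$reference)$slope
  qy <- quantum_yield(mF, mR, n_F = 1.334, n_r = 1.361, phi_r = 0.54)
  expect_equal(qy$phi, 0.09, tolerance = 1e-12)
  expect_warning(simulate_dilution_series(0.09,
                                          absorbances = seq(0.03, 0.15, 0.03)),
                 "inner-filter")
})

test_that("MSA fixture reproduces requested methionine statistics", {
  none <- make_msa_fixture(50, 10, met_freq_profile = 0, seed = 1)
  expect_false(any(none$seqs == "M"))

  # binomial sampling: observed frequency within 3 SE of the probability
  n <- 10000
  aln <- make_msa_fixture(n, 5, met_freq_profile = c(0.2, 0, 0, 0, 0),
                          seed = 2)
  body <- aln$seqs[-1, , drop = FALSE]  # drop the reference row
  obs <- mean(body[, 1] == "M")
  expect_lt(abs(obs - 0.2), 3 * sqrt(0.2 * 0.8 / n))

  cons <- c("2" = "C", "4" = "Q")
  degraded <- make_msa_fixture(200, 6, met_freq_profile = 0,
                               conserved_cols = cons,
                               degrade_fraction = 0.5, n_violations = 2,
                               seed = 3)
  bad <- rowSums(degraded$seqs[-1, c(2, 4)] !=
                   matrix(rep(c("C", "Q"), each = 200), 200)) >= 2
  expect_equal(mean(bad), 0.5, tolerance = 0.01)
})
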
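test_that("Nernst fraction and potential are exact inverses with known anchors", {
  expect_equal(nernst_fraction_reduced(-252, -252, 2, 295.15), 0.5)
  # one natural-log unit below the midpoint: f_red = e/(1+e)
  slope <- nernst_slope_mv(2, 295.15)
  expect_equal(slope, 12.717, tolerance = 1e-4)
  expect_equal(nernst_fraction_reduced(-252 - slope, -252, 2, 295.15),
               exp(1) / (1 + exp(1)), tolerance = 1e-12)
  expect_equal(round(nernst_fraction_reduced(-252 - 12.717, -252, 2, 295.15), 4),
               0.7311)
  expect_equal(nernst_fraction_reduced(1e6, -252, 2, 295.15), 0)
  expect_equal(nernst_fraction_reduced(-1e6, -252, 2, 295.15), 1)

  expect_equal(potential_from_fractions(0.5, 0.5, -252, 2, 295.15), -252)
  expect_equal(potential_from_fractions(0.7311, 0.2689, -252, 2, 295.15),
               -264.72, tolerance = 0.01)
  expect_error(potential_from_fractions(1, 0, -252, 2, 295.15),
               "singularity", class = "lov_validation_error")

  # inverse-pair identity over random draws
  set.seed(1)
  for (i in 1:50) {
    E0 <- runif(1, -320, -200); E <- E0 + runif(1, -40, 40)
    z <- sample(1:2, 1); Tk <- runif(1, 285, 310)
    f <- nernst_fraction_reduced(E, E0, z, Tk)
    expect_equal(potential_from_fractions(f, 1 - f, E0, z, Tk), E,
                 tolerance = 1e-12)
  }
  # strict monotone decrease in E
  E <- seq(-320, -200, 0.5)
  expect_true(all(diff(nernst_fraction_reduced(E, -260, 2, 295.15)) < 0))
})

test_that("spectral unmixing recovers mixture fractions and flags absent species", {
  refs <- make_reference_spectra("flavin_LOV")
  grid <- refs$analyte_ox$wavelengths
  pure <- spectrum(grid, refs$analyte_ox$values)
  u <- unmix_fractions(pure, refs, "analyte")
  expect_equal(u$f_ox, 1, tolerance = 1e-10)
  expect_equal(u$f_red, 0, tolerance = 1e-10)

  mix <- spectrum(grid, 0.3 * refs$analyte_ox$values +
                    0.7 * refs$analyte_red$values)
  u2 <- unmix_fractions(mix, refs, "analyte")
  expect_equal(u2$f_ox, 0.3, tolerance = 1e-10)
  expect_equal(u2$f_red, 0.7, tolerance = 1e-10)
  expect_equal(u2$f_ox + u2$f_red, 1)

  # indicator-only spectrum: analyte not detectable
  ind_only <- spectrum(grid, 0.25 * refs$indicator_ox$values)
  expect_error(unmix_fractions(ind_only, refs, "analyte"),
               "not detectable", class = "lov_validation_error")
})

test_that("unmixing agrees with a brute-force grid-search oracle under noise", {
  refs <- make_reference_spectra("flavin_LOV")
  grid <- refs$analyte_ox$wavelengths
  set.seed(7)
  for (i in 1:10) {
    f_ox_true <- runif(1, 0.1, 0.9)
    scale <- runif(1, 0.3, 0.6)
    vals <- scale * (f_ox_true * refs$analyte_ox$values +
                       (1 - f_ox_true) * refs$analyte_red$values) +
      rnorm(length(grid), 0, 0.002)
    u <- unmix_fractions(spectrum(grid, pmax(vals, 0)), refs, "analyte")
    oracle <- grid_unmix_oracle(pmax(vals, 0), refs$analyte_ox$values,
                                refs$analyte_red$values, scale)
    expect_lt(abs(u$f_ox - oracle), 2e-3)
    expect_lt(abs(u$f_ox - f_ox_true), 0.02)
  }
})

test_that("per-timepoint fractions match simulation truth; legacy mode is close", {
  refs <- make_reference_spectra("flavin_LOV")
  sim <- simulate_titration(titration_sim_params(noise_sd = 0,
                                                 n_timepoints = 40), refs)
  fr <- fractions_over_time(sim$series, refs)
  expect_equal(fr$analyte$f_red, sim$truth$analyte$f_red, tolerance = 1e-9)
  expect_equal(fr$indicator$f_red, sim$truth$indicator$f_red,
               tolerance = 1e-9)
  # fully oxidized start
  expect_gt(fr$analyte$f_ox[1], 0.99)
  expect_gt(fr$indicator$f_ox[1], 0.99)

  legacy <- fractions_over_time(sim$series, refs, mode = "two_wavelength")
  expect_lt(max(abs(legacy$analyte$f_red - sim$truth$analyte$f_red)), 0.02)
  expect_lt(max(abs(legacy$indicator$f_red - sim$truth$indicator$f_red)),
            0.02)
})

test_that("midpoint fit is exact on equilibrium data and self-consistent", {
  cfg <- default_config()
  refs <- make_reference_spectra("flavin_LOV")
  sim <- simulate_titration(titration_sim_params(noise_sd = 0), refs)
  fr <- fractions_over_time(sim$series, refs)

  # indicator regressed against itself: slope 1, offset 0, E0 = Er0
  self <- fit_midpoint(fr$indicator, fr$indicator, cfg)
  expect_equal(self$slope, 1, tolerance = 1e-12)
  expect_equal(self$offset_mv, 0, tolerance = 1e-9)
  expect_equal(self$E0_mv, -252, tolerance = 1e-9)

  fit <- fit_midpoint(fr$analyte, fr$indicator, cfg)
  expect_equal(fit$E0_mv, -278, tolerance = 1e-6)
  expect_equal(fit$slope, 1, tolerance = 1e-6)
  expect_true(fit$qc_pass)
})

test_that("noiseless midpoint recovery is exact for random generating parameters", {
  refs <- make_reference_spectra("flavin_LOV", seq(320, 650, 2))
  set.seed(31)
  for (i in 1:6) {
    E0 <- runif(1, -300, -255)
    tau <- runif(1, 3000, 12000)
    p <- titration_sim_params(analyte_E0_mv = E0, noise_sd = 0,
                              tau_s = tau, E_end_mv = -420,
                              duration_s = 6 * tau, n_timepoints = 150)
    sim <- simulate_titration(p, refs)
    fr <- fractions_over_time(sim$series, refs)
    fit <- fit_midpoint(fr$analyte, fr$indicator)
    expect_equal(fit$E0_mv, E0, tolerance = 1e-6)
    expect_equal(fit$slope, 1, tolerance = 1e-6)
  }
})

test_that("midpoint estimates are reproducible within 3 mV at default noise", {
  refs <- make_reference_spectra("flavin_LOV")
  e0s <- vapply(1:6, function(s) {
    sim <- simulate_titration(titration_sim_params(seed = s), refs)
    fr <- fractions_over_time(sim$series, refs)
    fit_midpoint(fr$analyte, fr$indicator)$E0_mv
  }, numeric(1))
  expect_lt(max(abs(e0s - -278)), 3)
  expect_lt(diff(range(e0s)), 3)
})

test_that("equilibration lag slows the analyte and trips the slope QC", {
  refs <- make_reference_spectra("flavin_LOV")
  lag <- simulate_titration(titration_sim_params(noise_sd = 0,
                                                 k_eq = 2e-4), refs)
  fr <- fractions_over_time(lag$series, refs)
  fit <- fit_midpoint(fr$analyte, fr$indicator)
  expect_false(fit$qc_pass)
  expect_gt(fit$slope, 1.2)
})

test_that("midpoint fit demands overlapping transitions", {
  cfg <- default_config()
  # analyte far more reducing than the window the indicator covers
  t <- seq(0, 100, length.out = 20)
  an <- fraction_series(t, rep(0.999, 20), rep(0.001, 20), "analyte")
  ind <- fraction_series(t, seq(0.9, 0.1, length.out = 20),
                         1 - seq(0.9, 0.1, length.out = 20), "indicator")
  expect_error(fit_midpoint(an, ind, cfg), "insufficient overlap",
               class = "lov_validation_error")
})

test_that("midpoint shift summaries use the variant-minus-wild-type convention", {
  s <- summarize_midpoint_shifts(-278, c(-260, -236))
  expect_equal(unname(s$delta_E0), c(18, 42))
  expect_equal(s$mean_delta_E0, 30)
  expect_equal(s$max_delta_E0, 42)
  expect_equal(summarize_midpoint_shifts(-278, -278)$delta_E0[[1]], 0)
  expect_error(summarize_midpoint_shifts(-278, numeric(0)),
               class = "lov_validation_error")
})
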
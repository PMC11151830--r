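#' @title Synthetic-data generators
#' @description Forward models that generate every input the analysis
#'   consumes -- titration spectra, photocycle traces, Arrhenius rate
#'   series, fluorescence dilution series, and LOV-like alignments -- with
#'   known ground truth, so each pipeline stage can be validated by
#'   parameter recovery.
#' @name synthetic
NULL

gaussian_band <- function(wl, center, width, height) {
  height * exp(-0.5 * ((wl - center) / width)^2)
}

#' Basis spectra of redox species
#'
#' `reference_set()` bundles the four basis spectra needed for spectral
#' unmixing of a dye-coupled titration: analyte oxidized/reduced and
#' indicator oxidized/reduced, on one wavelength grid, plus the indicator
#' midpoint potential and electron number.
#'
#' @param analyte_ox,analyte_red,indicator_ox,indicator_red
#'   [spectrum()] objects on a common grid, all values >= 0.
#' @param indicator_midpoint_mv Indicator midpoint potential, mV vs NHE.
#' @param z Electron number of the couples (default 2).
#' @return Object of class `lov_reference_set`.
#' @export
reference_set <- function(analyte_ox, analyte_red, indicator_ox,
                          indicator_red, indicator_midpoint_mv = -252,
                          z = 2L) {
  sp <- list(analyte_ox = analyte_ox, analyte_red = analyte_red,
             indicator_ox = indicator_ox, indicator_red = indicator_red)
  stopifnot(all(vapply(sp, inherits, logical(1), "lov_spectrum")))
  grid <- analyte_ox$wavelengths
  same <- vapply(sp, function(s) {
    length(s$wavelengths) == length(grid) && all(s$wavelengths == grid)
  }, logical(1))
  if (!all(same)) stop_validation("reference spectra must share one grid")
  if (any(vapply(sp, function(s) any(s$values < 0), logical(1)))) {
    stop_validation("reference spectra must be non-negative")
  }
  structure(c(sp, list(indicator_midpoint_mv = indicator_midpoint_mv,
                       z = as.integer(z))),
            class = "lov_reference_set")
}

#' @export
print.lov_reference_set <- function(x, ...) {
  cat(sprintf(
    "<lov_reference_set> grid %.0f-%.0f nm, indicator midpoint %g mV, z = %d\n",
    min(x$analyte_ox$wavelengths), max(x$analyte_ox$wavelengths),
    x$indicator_midpoint_mv, x$z))
  invisible(x)
}

#' Generate idealized reference spectra
#'
#' Builds Gaussian-mixture basis spectra emulating the species observed in
#' dye-coupled flavin titrations. `flavin_LOV`: protein-bound FMN with the
#' vibronically structured triple absorbance peak around 450 nm in the
#' oxidized quinone state and a near-UV hydroquinone band with negligible
#' absorbance above 430 nm when reduced. `riboflavin`: free flavin with the
#' same band positions but washed-out vibronic structure. Both kinds are
#' returned as a complete [reference_set()] including a
#' phenosafranine-like indicator pair (oxidized band peaking at 520 nm,
#' reduced form transparent in the visible). `phenosafranine_pair` returns
#' only the indicator pair as a list.
#'
#' Spectra are normalized to unit peak height; concentration scale factors
#' are applied at simulation time.
#'
#' @param kind `"flavin_LOV"`, `"riboflavin"`, or `"phenosafranine_pair"`.
#' @param grid Wavelength grid in nm; must cover the flavin (around 450 nm)
#'   and indicator (around 520 nm) bands.
#' @param indicator_midpoint_mv Midpoint of the indicator couple, mV vs NHE.
#' @return A `lov_reference_set`, or for `phenosafranine_pair` a list with
#'   elements `ox` and `red`.
#' @export
#' @examples
#' refs <- make_reference_spectra("flavin_LOV")
#' refs
make_reference_spectra <- function(kind = c("flavin_LOV", "riboflavin",
                                            "phenosafranine_pair"),
                                   grid = seq(300, 700, by = 1),
                                   indicator_midpoint_mv = -252) {
  kind <- match.arg(kind)
  if (min(grid) > 320 || max(grid) < 600) {
    stop_validation("grid must cover the flavin and indicator bands (roughly 320-600 nm)")
  }
  ind_ox <- spectrum(grid, gaussian_band(grid, 520, 28, 1.0),
                     label = "indicator oxidized")
  ind_red <- spectrum(grid, gaussian_band(grid, 330, 20, 0.05),
                      label = "indicator reduced")
  if (kind == "phenosafranine_pair") {
    return(list(ox = ind_ox, red = ind_red))
  }
  an_ox_vals <- if (kind == "flavin_LOV") {
    gaussian_band(grid, 372, 16, 0.85) + gaussian_band(grid, 426, 9, 0.72) +
      gaussian_band(grid, 449, 7.5, 1.0) + gaussian_band(grid, 473, 8, 0.62)
  } else {
    gaussian_band(grid, 372, 17, 0.88) + gaussian_band(grid, 445, 13, 1.0) +
      gaussian_band(grid, 472, 10, 0.42)
  }
  an_red <- spectrum(grid, gaussian_band(grid, 350, 28, 0.9),
                     label = "analyte reduced (hydroquinone)")
  reference_set(
    analyte_ox = spectrum(grid, an_ox_vals,
                          label = paste(kind, "oxidized (quinone)")),
    analyte_red = an_red,
    indicator_ox = ind_ox, indicator_red = ind_red,
    indicator_midpoint_mv = indicator_midpoint_mv
  )
}

#' Parameters of a simulated chemical-reduction titration
#'
#' The forward model assumes a slowly, monotonically decreasing solution
#' potential driven by excess chemical reductant, with analyte and
#' indicator fractions tracking it through their Nernst equilibria
#' (mediator-facilitated equilibration). The potential trajectory is a
#' single exponential relaxation from `E_start_mv` to `E_end_mv` with time
#' constant `tau_s`. Defaults span both transitions of a flavin analyte
#' (around -280 mV) and a phenosafranine indicator (-252 mV) over an
#' eight-hour reduction, matching the "several hours to complete
#' reduction" regime of bench titrations.
#'
#' @param analyte_E0_mv True analyte midpoint, mV vs NHE.
#' @param indicator_Er0_mv Indicator midpoint, mV vs NHE.
#' @param z_analyte,z_indicator Electron numbers (1 or 2).
#' @param temperature Kelvin.
#' @param E_start_mv,E_end_mv,tau_s Potential trajectory: start, asymptote
#'   (must be below start), relaxation time constant (s).
#' @param duration_s Total simulated time (s).
#' @param n_timepoints Number of spectra (>= 10).
#' @param noise_sd Additive Gaussian noise on each absorbance value (AU).
#' @param conc_analyte,conc_indicator Concentration scale factors applied
#'   to the unit-peak basis spectra (peak AU contributed by each species).
#' @param k_eq Optional first-order equilibration rate (s^-1). When set,
#'   analyte fractions relax toward their Nernst equilibrium with this rate
#'   instead of equilibrating instantly, emulating a reduction that
#'   outpaces redox equilibration (the pathology that trips the slope QC).
#' @param seed Integer seed.
#' @return Object of class `lov_titration_params`.
#' @export
titration_sim_params <- function(analyte_E0_mv = -278,
                                 indicator_Er0_mv = -252,
                                 z_analyte = 2L, z_indicator = 2L,
                                 temperature = 295.15,
                                 E_start_mv = -100, E_end_mv = -400,
                                 tau_s = 7200,
                                 duration_s = 28800, n_timepoints = 200L,
                                 noise_sd = 0.002,
                                 conc_analyte = 0.45, conc_indicator = 0.25,
                                 k_eq = NULL, seed = 1L) {
  if (E_end_mv >= E_start_mv) {
    stop_validation("E_end_mv must be below E_start_mv (reduction proceeds downward)")
  }
  if (tau_s <= 0) stop_validation("tau_s must be positive")
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  if (n_timepoints < 10) stop_validation("n_timepoints must be >= 10")
  if (!z_analyte %in% c(1L, 2L) || !z_indicator %in% c(1L, 2L)) {
    stop_validation("electron numbers must be 1 or 2")
  }
  if (!is.null(k_eq) && k_eq <= 0) stop_validation("k_eq must be positive")
  structure(
    list(analyte_E0_mv = analyte_E0_mv, indicator_Er0_mv = indicator_Er0_mv,
         z_analyte = as.integer(z_analyte),
         z_indicator = as.integer(z_indicator),
         temperature = temperature, E_start_mv = E_start_mv,
         E_end_mv = E_end_mv, tau_s = tau_s, duration_s = duration_s,
         n_timepoints = as.integer(n_timepoints), noise_sd = noise_sd,
         conc_analyte = conc_analyte, conc_indicator = conc_indicator,
         k_eq = k_eq, seed = as.integer(seed)),
    class = "lov_titration_params"
  )
}

#' Solution potential at time t
#'
#' Exponential relaxation `E(t) = E_end + (E_start - E_end) exp(-t/tau)`:
#' monotone decreasing, `E(0) = E_start`, asymptote `E_end`.
#'
#' @param params A [titration_sim_params()].
#' @param t Time(s) in seconds, >= 0.
#' @return Potential(s) in mV vs NHE.
#' @export
potential_trajectory <- function(params, t) {
  stopifnot(inherits(params, "lov_titration_params"))
  if (any(t < 0)) stop_validation("t must be >= 0")
  params$E_end_mv +
    (params$E_start_mv - params$E_end_mv) * exp(-t / params$tau_s)
}

# First-order relaxation of f_red toward the moving Nernst equilibrium,
# integrated with exact exponential updates on a fine substep grid.
lagged_fractions <- function(times, E_of_t, E0, z, temperature, k_eq,
                             n_sub = 20L) {
  f <- numeric(length(times))
  f_cur <- nernst_fraction_reduced(E_of_t(0), E0, z, temperature)
  t_prev <- 0
  for (i in seq_along(times)) {
    dt_total <- times[i] - t_prev
    if (dt_total > 0) {
      dt <- dt_total / n_sub
      for (s in seq_len(n_sub)) {
        t_mid <- t_prev + (s - 0.5) * dt
        f_eq <- nernst_fraction_reduced(E_of_t(t_mid), E0, z, temperature)
        f_cur <- f_eq + (f_cur - f_eq) * exp(-k_eq * dt)
      }
    }
    f[i] <- f_cur
    t_prev <- times[i]
  }
  f
}

#' Simulate a dye-coupled reduction titration
#'
#' At each timepoint the analyte and indicator oxidized/reduced fractions
#' are the Nernst equilibrium values at the current solution potential
#' (instant equilibration, emulating a redox mediator), or relax toward
#' them with rate `k_eq` when the equilibration-lag mode is enabled in
#' `params`. The observed spectrum is the fraction- and
#' concentration-weighted sum of the four basis spectra plus i.i.d.
#' Gaussian noise. Deterministic under a fixed seed.
#'
#' @param params A [titration_sim_params()].
#' @param refs A [reference_set()] (see [make_reference_spectra()]).
#' @return A list with `series` (a [spectral_timeseries()]) and `truth`
#'   (times, potential, and exact [fraction_series()] for both species).
#' @export
#' @examples
#' sim <- simulate_titration(titration_sim_params(noise_sd = 0),
#'                           make_reference_spectra("flavin_LOV"))
#' sim$series
simulate_titration <- function(params, refs) {
  stopifnot(inherits(params, "lov_titration_params"),
            inherits(refs, "lov_reference_set"))
  times <- seq(0, params$duration_s, length.out = params$n_timepoints)
  E <- potential_trajectory(params, times)
  f_red_ind <- nernst_fraction_reduced(E, params$indicator_Er0_mv,
                                       params$z_indicator,
                                       params$temperature)
  if (is.null(params$k_eq)) {
    f_red_an <- nernst_fraction_reduced(E, params$analyte_E0_mv,
                                        params$z_analyte,
                                        params$temperature)
  } else {
    f_red_an <- lagged_fractions(
      times, function(t) potential_trajectory(params, t),
      params$analyte_E0_mv, params$z_analyte, params$temperature,
      params$k_eq)
  }
  grid <- refs$analyte_ox$wavelengths
  basis <- cbind(refs$analyte_ox$values, refs$analyte_red$values,
                 refs$indicator_ox$values, refs$indicator_red$values)
  set.seed(params$seed)
  spectra <- lapply(seq_along(times), function(i) {
    coef <- c(params$conc_analyte * (1 - f_red_an[i]),
              params$conc_analyte * f_red_an[i],
              params$conc_indicator * (1 - f_red_ind[i]),
              params$conc_indicator * f_red_ind[i])
    vals <- as.numeric(basis %*% coef)
    if (params$noise_sd > 0) {
      vals <- vals + stats::rnorm(length(grid), 0, params$noise_sd)
    }
    spectrum(grid, vals)
  })
  list(
    series = spectral_timeseries(times, spectra,
                                 temperature = params$temperature),
    truth = list(
      times = times, E_mv = E,
      analyte = fraction_series(times, 1 - f_red_an, f_red_an, "analyte"),
      indicator = fraction_series(times, 1 - f_red_ind, f_red_ind,
                                  "indicator"),
      params = params)
  )
}

#' Simulate a single-exponential photocycle trace
#'
#' `recovery`: absorbance at 450 nm rising back to the dark baseline after
#' illumination ceases, `A(t) = baseline - amplitude exp(-k t)`.
#' `photoactivation`: decay under constant illumination with observed rate
#' `k1 + k_rec` toward the photostationary plateau; the plateau is the
#' two-state steady-state dark fraction `k_rec/(k1 + k_rec)` times the dark
#' baseline, which makes the amplitude terms self-consistent with the
#' two-state model.
#'
#' @param kind `"recovery"` or `"photoactivation"`.
#' @param rates For recovery, a single rate `k` (s^-1); for
#'   photoactivation, `c(k1, k_rec)` (s^-1), both > 0 (k_rec may be 0).
#' @param times Sampling times (s), strictly increasing.
#' @param baseline Dark-adapted signal level (AU).
#' @param amplitude Recovery amplitude (AU); ignored for photoactivation,
#'   where amplitudes follow from the two-state steady state.
#' @param noise_sd Additive Gaussian noise (signal units).
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @param temperature Kelvin.
#' @param illumination_intensity mW cm^-2 recorded on photoactivation
#'   traces (default 3).
#' @return A [kinetic_trace()].
#' @export
simulate_exponential_trace <- function(kind = c("recovery", "photoactivation"),
                                       rates,
                                       times = seq(0, 300, by = 2),
                                       baseline = 0.45, amplitude = 0.40,
                                       noise_sd = 0, seed = 1L,
                                       temperature = 295.15,
                                       illumination_intensity = 3) {
  kind <- match.arg(kind)
  if (any(rates < 0)) stop_validation("rates must be non-negative")
  if (kind == "recovery") {
    if (length(rates) != 1 || rates <= 0) {
      stop_validation("recovery takes a single positive rate")
    }
    signal <- baseline - amplitude * exp(-rates * times)
    intensity <- 0
  } else {
    if (length(rates) != 2 || rates[1] <= 0) {
      stop_validation("photoactivation takes rates c(k1, k_rec) with k1 > 0")
    }
    k_obs <- sum(rates)
    pss <- rates[2] / k_obs
    signal <- baseline * (pss + (1 - pss) * exp(-k_obs * times))
    intensity <- illumination_intensity
  }
  if (noise_sd > 0) {
    set.seed(seed)
    signal <- signal + stats::rnorm(length(times), 0, noise_sd)
  }
  kinetic_trace(times, signal, temperature = temperature,
                illumination_intensity = intensity)
}

#' Simulate an Arrhenius rate-temperature series
#'
#' `k(T) = k_ref exp(-EA/R (1/T - 1/T_ref))` with optional multiplicative
#' lognormal noise of a given coefficient of variation (mean-one noise).
#'
#' @param EA_kj_mol Activation energy, kJ mol^-1, >= 0.
#' @param k_ref Rate at `T_ref`, s^-1.
#' @param temperatures Kelvin, within 280-320 K.
#' @param T_ref Reference temperature, kelvin.
#' @param noise_cv Coefficient of variation of the lognormal noise.
#' @param seed Integer seed.
#' @return data.frame with columns `temperature` (K) and `k` (s^-1).
#' @export
simulate_arrhenius_series <- function(EA_kj_mol, k_ref,
                                      temperatures = c(295.15, 299.15,
                                                       303.15, 307.15,
                                                       311.15),
                                      T_ref = 295.15,
                                      noise_cv = 0, seed = 1L) {
  if (EA_kj_mol < 0) stop_validation("EA_kj_mol must be >= 0")
  if (k_ref <= 0) stop_validation("k_ref must be positive")
  if (any(temperatures < 280) || any(temperatures > 320)) {
    stop_validation("temperatures must lie within 280-320 K")
  }
  k <- k_ref * exp(-(EA_kj_mol * 1000) / GAS_CONSTANT *
                     (1 / temperatures - 1 / T_ref))
  if (noise_cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    k <- k * stats::rlnorm(length(k), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  data.frame(temperature = temperatures, k = k)
}

#' Simulate sample and reference fluorescence dilution series
#'
#' Generates two dilution series -- sample and reference fluorophore -- in
#' the linear (optically thin) regime, with integrated fluorescence
#' proportional to absorbance. The sample slope is chosen so that the
#' slope-ratio quantum-yield relation returns exactly `phi_true` given
#' `phi_ref` and the refractive indices.
#'
#' @param phi_true True sample quantum yield, in (0, 1].
#' @param phi_ref Reference quantum yield (default 0.54, coumarin 153 in
#'   ethanol).
#' @param absorbances Absorbance values at the excitation wavelength
#'   (default 0.02, 0.04, ..., 0.1; a warning is issued above 0.15 where
#'   inner-filter effects bias the linear model).
#' @param n_sample,n_ref Refractive indices of the sample (aqueous buffer,
#'   1.334) and reference (ethanol, 1.361) solvents.
#' @param reference_slope Reference fluorescence-vs-absorbance slope in
#'   arbitrary units per AU (sets the overall intensity scale).
#' @param noise_cv Multiplicative lognormal noise on fluorescence values.
#' @param seed Integer seed.
#' @return List with `sample` and `reference`, each a [dilution_series()].
#' @export
simulate_dilution_series <- function(phi_true, phi_ref = 0.54,
                                     absorbances = seq(0.02, 0.1, by = 0.02),
                                     n_sample = 1.334, n_ref = 1.361,
                                     reference_slope = 1e4,
                                     noise_cv = 0, seed = 1L) {
  if (phi_true <= 0 || phi_true > 1) stop_validation("phi_true must be in (0, 1]")
  if (phi_ref <= 0 || phi_ref > 1) stop_validation("phi_ref must be in (0, 1]")
  if (max(absorbances) > 0.1) {
    warning("absorbances above 0.1: approaching the inner-filter regime, linearity doubtful")
  }
  sample_slope <- reference_slope * (phi_true / phi_ref) *
    (n_ref^2 / n_sample^2)
  set.seed(seed)
  noisy <- function(slope) {
    f <- slope * absorbances
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      f <- f * stats::rlnorm(length(f), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    f
  }
  list(
    sample = dilution_series(absorbances, noisy(sample_slope),
                             refractive_index = n_sample),
    reference = dilution_series(absorbances, noisy(reference_slope),
                                refractive_index = n_ref)
  )
}

#' Generate a LOV-like multiple sequence alignment fixture
#'
#' Each sequence draws methionine at column `j` with probability
#' `met_freq_profile[j]` and otherwise a uniformly random non-methionine
#' residue. Columns listed in `conserved_cols` carry their expected residue
#' deterministically, except in a `degrade_fraction` of sequences, which
#' receive `n_violations` mismatches at randomly chosen conserved columns
#' so that the conserved-residue filter has something to remove. An
#' ungapped reference row carrying all conserved residues is prepended so
#' the alignment can be mapped to reference numbering.
#'
#' @param n_seqs Number of (non-reference) sequences.
#' @param n_cols Alignment width.
#' @param met_freq_profile Per-column methionine probabilities in \[0,1\]
#'   (recycled scalar allowed).
#' @param conserved_cols Named character vector: names are column indices,
#'   values the conserved residue (e.g. `c("3" = "C", "7" = "Q")`).
#' @param degrade_fraction Fraction of sequences given conserved-site
#'   violations.
#' @param n_violations Mismatches introduced per degraded sequence
#'   (default 3, enough to fail an 8-of-10 filter).
#' @param seed Integer seed.
#' @param reference_id Identifier of the prepended reference row.
#' @return A `lov_alignment`.
#' @export
make_msa_fixture <- function(n_seqs, n_cols, met_freq_profile = 0.05,
                             conserved_cols = character(0),
                             degrade_fraction = 0, n_violations = 3L,
                             seed = 1L, reference_id = "reference") {
  p <- rep_len(met_freq_profile, n_cols)
  if (any(p < 0) || any(p > 1)) {
    stop_validation("met_freq_profile probabilities must lie in [0, 1]")
  }
  if (degrade_fraction < 0 || degrade_fraction > 1) {
    stop_validation("degrade_fraction must lie in [0, 1]")
  }
  cons_idx <- as.integer(names(conserved_cols))
  if (length(cons_idx) && (any(is.na(cons_idx)) || any(cons_idx < 1) ||
                           any(cons_idx > n_cols))) {
    stop_validation("conserved_cols names must be valid column indices")
  }
  if (length(cons_idx) && n_violations > length(cons_idx)) {
    stop_validation("n_violations exceeds the number of conserved columns")
  }
  non_met <- setdiff(AA_ALPHABET, "M")
  set.seed(seed)
  mat <- matrix("", nrow = n_seqs, ncol = n_cols)
  for (j in seq_len(n_cols)) {
    is_met <- stats::runif(n_seqs) < p[j]
    mat[, j] <- ifelse(is_met, "M",
                       sample(non_met, n_seqs, replace = TRUE))
  }
  if (length(cons_idx)) {
    mat[, cons_idx] <- matrix(rep(toupper(unname(conserved_cols)),
                                  each = n_seqs),
                              nrow = n_seqs)
    n_degrade <- round(degrade_fraction * n_seqs)
    if (n_degrade > 0) {
      degraded <- sample.int(n_seqs, n_degrade)
      for (i in degraded) {
        hit <- sample(seq_along(cons_idx), n_violations)
        for (h in hit) {
          mat[i, cons_idx[h]] <- sample(
            setdiff(non_met, toupper(conserved_cols[h])), 1)
        }
      }
    }
  }
  ref <- rep("A", n_cols)
  ref[cons_idx] <- toupper(unname(conserved_cols))
  mat <- rbind(ref, mat)
  ids <- c(reference_id, sprintf("seq%05d", seq_len(n_seqs)))
  make_alignment(ids, apply(mat, 1, paste0, collapse = ""))
}
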
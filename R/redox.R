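#' Reduced fraction at a given solution potential
#'
#' The Nernst relation `E = E0 - RT/zF ln(f_red/f_ox)` inverted for the
#' reduced fraction: `f_red = 1 / (1 + exp(zF (E - E0) / RT))`. Strictly
#' decreasing in `E`; equals 0.5 at the midpoint. Arguments are clipped so
#' extreme potentials return 0 or 1 without overflow.
#'
#' @param E Solution potential(s), mV vs NHE.
#' @param E0 Midpoint potential of the couple, mV vs NHE.
#' @param z Electron number (1 or 2).
#' @param temperature Kelvin.
#' @return Reduced fraction(s) in \[0, 1\].
#' @export
#' @examples
#' nernst_fraction_reduced(-252, -252, z = 2, temperature = 295.15)  # 0.5
nernst_fraction_reduced <- function(E, E0, z, temperature) {
  slope <- nernst_slope_mv(z, temperature)
  x <- pmin(pmax((E - E0) / slope, -700), 700)
  1 / (1 + exp(x))
}

#' Solution potential from oxidized/reduced fractions
#'
#' Direct Nernst form `E = E0 - RT/zF ln(f_red/f_ox)`; exact inverse of
#' [nernst_fraction_reduced()]. Fractions of exactly 0 or 1 are a log
#' singularity and rejected -- callers must window the usable range.
#'
#' @param f_red,f_ox Fractions in (0, 1) summing to 1.
#' @param E0 Midpoint potential, mV vs NHE.
#' @param z Electron number.
#' @param temperature Kelvin.
#' @return Potential(s) in mV vs NHE.
#' @export
potential_from_fractions <- function(f_red, f_ox, E0, z, temperature) {
  if (any(f_red <= 0) || any(f_red >= 1) || any(f_ox <= 0) || any(f_ox >= 1)) {
    stop_validation("fractions of 0 or 1 are a log singularity; window the data")
  }
  if (any(abs(f_red + f_ox - 1) > 1e-9)) {
    stop_validation("f_red + f_ox must equal 1")
  }
  E0 - nernst_slope_mv(z, temperature) * log(f_red / f_ox)
}

#' Spectral unmixing of one spectrum into redox species fractions
#'
#' Decomposes an observed absorbance spectrum into non-negative
#' least-squares coefficients over the four basis spectra of a
#' [reference_set()] (analyte ox/red, indicator ox/red), then renormalizes
#' the coefficient pair of the requested species to fractions summing
#' to 1. This generalizes single-wavelength indicator correction: the full
#' spectrum is used, so overlapping analyte and indicator bands are
#' separated by least squares rather than by subtraction at one
#' wavelength.
#'
#' @param spec A [spectrum()] on the reference grid.
#' @param refs A [reference_set()].
#' @param species `"analyte"` or `"indicator"`.
#' @return List with `f_ox`, `f_red` (summing to 1) and `residual`
#'   (root-mean-square misfit of the four-component model).
#' @export
unmix_fractions <- function(spec, refs, species = c("analyte", "indicator")) {
  species <- match.arg(species)
  stopifnot(inherits(spec, "lov_spectrum"),
            inherits(refs, "lov_reference_set"))
  grid <- refs$analyte_ox$wavelengths
  if (length(spec$wavelengths) != length(grid) ||
      !all(spec$wavelengths == grid)) {
    stop_validation("spectrum must be on the reference wavelength grid")
  }
  basis <- cbind(refs$analyte_ox$values, refs$analyte_red$values,
                 refs$indicator_ox$values, refs$indicator_red$values)
  fit <- pracma::lsqnonneg(basis, spec$values)
  coefs <- fit$x
  rss <- sum((spec$values - basis %*% coefs)^2)
  idx <- if (species == "analyte") 1:2 else 3:4
  pair <- coefs[idx]
  tot <- sum(pair)
  if (tot <= 1e-12 * max(sum(coefs), 1)) {
    stop_validation(sprintf("species not detectable: %s coefficients are ~0",
                            species))
  }
  list(f_ox = pair[1] / tot, f_red = pair[2] / tot,
       residual = sqrt(rss / length(grid)))
}

#' Oxidized/reduced fractions of analyte and indicator over a titration
#'
#' Applies [unmix_fractions()] to every spectrum of a titration time
#' series for both species. `mode = "full"` (canonical) unmixes the whole
#' spectrum against all four references. `mode = "two_wavelength"` is a
#' legacy procedure mirroring classic bench practice: the indicator
#' reduction is read from the absorbance at its band maximum (about
#' 520 nm, where the flavin contributes negligibly), the analyte signal at
#' 450 nm is corrected for the indicator contribution, and fractions
#' follow from a two-point calibration; species amplitudes are calibrated
#' from the first (fully oxidized) spectrum.
#'
#' Because a titration runs at constant total concentrations and starts
#' with both species fully oxidized, the full mode calibrates each
#' species' total spectral amplitude as the mean oxidized-form coefficient
#' over the first timepoints and computes fractions from the
#' well-determined oxidized-form coefficient, `f_ox(t) = c_ox(t) / c_total`. This avoids relying on the
#' reduced-form coefficients, which are nearly unidentifiable for species
#' whose reduced state is optically transparent (leuco dyes such as
#' phenosafranine), and is the spectrally resolved analogue of normalizing
#' the indicator band decay by its initial amplitude.
#'
#' @param series A [spectral_timeseries()].
#' @param refs A [reference_set()].
#' @param mode `"full"` or `"two_wavelength"`.
#' @param wl_analyte,wl_indicator Wavelengths (nm) used by the legacy
#'   two-wavelength mode.
#' @param n_calibration Number of initial timepoints used to calibrate the
#'   total amplitude of each species in full mode.
#' @return List with `analyte` and `indicator` [fraction_series()].
#' @export
fractions_over_time <- function(series, refs,
                                mode = c("full", "two_wavelength"),
                                wl_analyte = 450, wl_indicator = 520,
                                n_calibration = 3L) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "lov_spectral_timeseries"),
            inherits(refs, "lov_reference_set"))
  n <- length(series$times)
  if (mode == "full") {
    basis <- cbind(refs$analyte_ox$values, refs$analyte_red$values,
                   refs$indicator_ox$values, refs$indicator_red$values)
    grid <- refs$analyte_ox$wavelengths
    coefs <- matrix(NA_real_, n, 4)
    resid <- numeric(n)
    for (i in seq_len(n)) {
      s <- series$spectra[[i]]
      if (length(s$wavelengths) != length(grid) ||
          !all(s$wavelengths == grid)) {
        stop_validation(sprintf(
          "timepoint %d: spectrum not on the reference grid", i))
      }
      fit <- pracma::lsqnonneg(basis, s$values)
      coefs[i, ] <- fit$x
      resid[i] <- sqrt(sum((s$values - basis %*% fit$x)^2) / length(grid))
    }
    # Amplitude calibration from the head of the series, where the
    # standard experiment starts fully oxidized. The reduced-form head
    # coefficient is added only when it exceeds its own noise level
    # (estimated from the unmixing residual): for species whose reduced
    # state is optically transparent (leuco dyes such as phenosafranine)
    # that coefficient is noise-dominated and would bias the amplitude.
    head_idx <- seq_len(min(n_calibration, n))
    species_amp <- function(ox_col, red_col) {
      amp_ox <- mean(coefs[head_idx, ox_col])
      amp_red <- mean(coefs[head_idx, red_col])
      sigma_red <- mean(resid[head_idx]) * sqrt(length(grid)) /
        sqrt(sum(basis[, red_col]^2)) / sqrt(length(head_idx))
      amp_ox + if (amp_red > 3 * sigma_red) amp_red else 0
    }
    amp_an <- species_amp(1, 2)
    amp_ind <- species_amp(3, 4)
    if (amp_an <= 1e-12) stop_validation("species not detectable: analyte")
    if (amp_ind <= 1e-12) stop_validation("species not detectable: indicator")
    f_ox_an <- pmin(pmax(coefs[, 1] / amp_an, 0), 1)
    f_ox_ind <- pmin(pmax(coefs[, 3] / amp_ind, 0), 1)
    return(list(
      analyte = fraction_series(series$times, f_ox_an, 1 - f_ox_an,
                                "analyte"),
      indicator = fraction_series(series$times, f_ox_ind, 1 - f_ox_ind,
                                  "indicator")))
  }
  # legacy two-wavelength mode
  at <- function(s, wl) spectrum_at(s, wl)
  ref_at <- function(which, wl) spectrum_at(refs[[which]], wl)
  # calibrate species amplitudes from the first, fully oxidized spectrum:
  # solve A(450) = c_an ox_an(450) + c_ind ox_ind(450), same at 520 nm
  A0 <- c(at(series$spectra[[1]], wl_analyte),
          at(series$spectra[[1]], wl_indicator))
  M <- matrix(c(ref_at("analyte_ox", wl_analyte),
                ref_at("indicator_ox", wl_analyte),
                ref_at("analyte_ox", wl_indicator),
                ref_at("indicator_ox", wl_indicator)),
              2, 2, byrow = TRUE)
  conc <- solve(M, A0)
  c_an <- conc[1]; c_ind <- conc[2]
  if (c_an <= 0 || c_ind <= 0) {
    stop_validation("two-wavelength calibration failed: non-positive amplitude")
  }
  f_ind_ox <- f_an_ox <- numeric(n)
  for (i in seq_len(n)) {
    a_ind <- at(series$spectra[[i]], wl_indicator)
    # indicator from its band maximum (analyte contribution negligible there)
    span_i <- c_ind * (ref_at("indicator_ox", wl_indicator) -
                         ref_at("indicator_red", wl_indicator))
    f_io <- (a_ind - c_ind * ref_at("indicator_red", wl_indicator)) / span_i
    f_io <- min(max(f_io, 0), 1)
    # analyte signal corrected for the indicator contribution
    a_an <- at(series$spectra[[i]], wl_analyte) -
      c_ind * (f_io * ref_at("indicator_ox", wl_analyte) +
                 (1 - f_io) * ref_at("indicator_red", wl_analyte))
    span_a <- c_an * (ref_at("analyte_ox", wl_analyte) -
                        ref_at("analyte_red", wl_analyte))
    f_ao <- (a_an - c_an * ref_at("analyte_red", wl_analyte)) / span_a
    f_ind_ox[i] <- f_io
    f_an_ox[i] <- min(max(f_ao, 0), 1)
  }
  list(
    analyte = fraction_series(series$times, f_an_ox, 1 - f_an_ox,
                              "analyte"),
    indicator = fraction_series(series$times, f_ind_ox, 1 - f_ind_ox,
                                "indicator"))
}

#' Estimate the analyte midpoint potential by Nernst correlation
#'
#' For each usable timepoint, the Nernst log terms
#' `x = RT/zF ln(f_red/f_ox)` (analyte) and `y = RT/zF ln(f_r,red/f_r,ox)`
#' (indicator) are computed; equating the two Nernst relations gives
#' `y = x - (E0 - Er0)`, so an ordinary least-squares line of `y` on `x`
#' has unit slope and its intercept is `-(E0 - Er0)`. Timepoints where
#' either species lies outside the configured fraction window are dropped
#' (they sit on the log singularities and carry no information). Slopes
#' outside the QC bounds indicate insufficient redox equilibration and set
#' `qc_pass = FALSE`; a symmetric inverted-axes fit is computed as a
#' diagnostic and large disagreement is logged.
#'
#' @param analyte,indicator [fraction_series()] on shared timepoints.
#' @param config An [analysis_config()] supplying the indicator midpoint,
#'   z, temperature, fraction window and slope bounds.
#' @return Object of class `lov_redox_fit`: slope, `offset_mv`
#'   (`E0 - Er0`), `E0_mv`, `n_points_used`, `qc_pass`, residual summary,
#'   and the correlation table (`x`, `y` pairs).
#' @export
fit_midpoint <- function(analyte, indicator, config = analysis_config()) {
  stopifnot(inherits(analyte, "lov_fraction_series"),
            inherits(indicator, "lov_fraction_series"))
  if (length(analyte$times) != length(indicator$times) ||
      any(analyte$times != indicator$times)) {
    stop_validation("analyte and indicator series must share timepoints")
  }
  w <- config$fraction_window
  keep <- analyte$f_red > w[1] & analyte$f_red < w[2] &
    indicator$f_red > w[1] & indicator$f_red < w[2]
  if (sum(keep) < 5) {
    stop_validation("insufficient overlap of redox transitions (< 5 usable timepoints)")
  }
  slope_mv <- nernst_slope_mv(config$z, config$temperature_default)
  x <- slope_mv * log(analyte$f_red[keep] / analyte$f_ox[keep])
  y <- slope_mv * log(indicator$f_red[keep] / indicator$f_ox[keep])
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  offset_mv <- -unname(co[1])   # y = x - (E0 - Er0)
  slope <- unname(co[2])
  # inverted-axes diagnostic: slope of x on y should be ~1/slope
  inv <- stats::coef(stats::lm(x ~ y))[2]
  if (is.finite(inv) && abs(slope * inv - 1) > 0.2) {
    lov_log("fit_midpoint: regression-direction disagreement (slope %.3f, inverse %.3f)",
            slope, unname(inv))
  }
  qc <- slope >= config$slope_qc[1] & slope <= config$slope_qc[2]
  structure(
    list(slope = slope, offset_mv = offset_mv,
         E0_mv = config$indicator_midpoint_mv + offset_mv,
         Er0_mv = config$indicator_midpoint_mv,
         n_points_used = sum(keep), qc_pass = qc,
         residual_rms = sqrt(mean(stats::residuals(fit)^2)),
         slope_se = suppressWarnings(summary(fit)$coefficients[2, 2]),
         correlation = data.frame(time = analyte$times[keep], x = x, y = y)),
    class = "lov_redox_fit"
  )
}

#' @export
print.lov_redox_fit <- function(x, ...) {
  cat(sprintf(
    "<lov_redox_fit> E0 = %.1f mV vs NHE (offset %.1f mV from indicator %.0f mV)\n",
    x$E0_mv, x$offset_mv, x$Er0_mv))
  cat(sprintf("  slope %.3f (SE %.3f), %d points, QC %s\n",
              x$slope, x$slope_se, x$n_points_used,
              if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}

#' Summarize midpoint shifts of variants against a wild type
#'
#' Shift convention: `delta_E0 = variant - wild type` in mV, so positive
#' values mean a higher (less negative) midpoint potential, i.e. easier
#' reduction. Full precision is carried; rounding to integer mV is left to
#' the report layer.
#'
#' @param wild_type_E0 Wild-type midpoint, mV vs NHE.
#' @param variant_E0s Named (or unnamed) numeric vector of variant
#'   midpoints, mV vs NHE.
#' @return List with `delta_E0` (per variant), `mean_delta_E0`,
#'   `max_delta_E0`.
#' @export
summarize_midpoint_shifts <- function(wild_type_E0, variant_E0s) {
  if (length(variant_E0s) == 0) {
    stop_validation("variant_E0s must be nonempty")
  }
  delta <- variant_E0s - wild_type_E0
  list(delta_E0 = delta, mean_delta_E0 = mean(delta),
       max_delta_E0 = max(delta))
}
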
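#' Fluorescence dilution series
#'
#' Absorbance at the excitation wavelength and integrated fluorescence for
#' a series of dilutions of one fluorophore, used for the slope-ratio
#' determination of the relative fluorescence quantum yield. Absorbances
#' are kept at or below 0.15 so the optically thin linear relation between
#' absorbance and emission holds.
#'
#' @param absorbance Absorbance values at the excitation wavelength (AU).
#' @param fluorescence Integrated fluorescence intensities (arbitrary
#'   units), same length.
#' @param refractive_index Refractive index of the solvent.
#' @return Object of class `lov_dilution_series`.
#' @export
dilution_series <- function(absorbance, fluorescence, refractive_index) {
  absorbance <- as.numeric(absorbance)
  fluorescence <- as.numeric(fluorescence)
  if (length(absorbance) != length(fluorescence)) {
    stop_validation("absorbance and fluorescence must have equal length")
  }
  if (length(absorbance) < 3) {
    stop_validation("a dilution series needs >= 3 points")
  }
  if (any(absorbance > 0.15)) {
    stop_validation("absorbance above 0.15: outside the linear (optically thin) regime")
  }
  if (refractive_index <= 0) {
    stop_validation("refractive_index must be positive")
  }
  structure(
    list(absorbance = absorbance, fluorescence = fluorescence,
         refractive_index = refractive_index),
    class = "lov_dilution_series"
  )
}

#' Integrate an emission spectrum over a wavelength range
#'
#' Trapezoidal integral of the signal over `range`, e.g. the 450-700 nm
#' window of flavin emission.
#'
#' @param spec A [spectrum()].
#' @param range Length-2 nm pair inside the spectrum grid.
#' @return Integrated intensity (signal units times nm).
#' @export
integrate_emission <- function(spec, range = c(450, 700)) {
  stopifnot(inherits(spec, "lov_spectrum"))
  if (range[1] >= range[2]) stop_validation("range must be increasing")
  if (range[1] < min(spec$wavelengths) || range[2] > max(spec$wavelengths)) {
    stop_validation("integration range outside the spectrum grid")
  }
  inside <- spec$wavelengths > range[1] & spec$wavelengths < range[2]
  wl <- c(range[1], spec$wavelengths[inside], range[2])
  vals <- c(spectrum_at(spec, range[1]), spec$values[inside],
            spectrum_at(spec, range[2]))
  pracma::trapz(wl, vals)
}

#' Fit the fluorescence-vs-absorbance slope of a dilution series
#'
#' Least-squares slope of integrated fluorescence against absorbance. By
#' default the intercept is free (instrument offsets exist); a
#' zero-intercept fit is available via `intercept = "zero"`.
#'
#' @param series A [dilution_series()].
#' @param intercept `"free"` (default) or `"zero"`.
#' @return List with `slope`, `slope_se`, `intercept`.
#' @export
fit_dilution_slope <- function(series, intercept = c("free", "zero")) {
  intercept <- match.arg(intercept)
  stopifnot(inherits(series, "lov_dilution_series"))
  df <- data.frame(a = series$absorbance, f = series$fluorescence)
  fit <- if (intercept == "free") stats::lm(f ~ a, df) else
    stats::lm(f ~ a - 1, df)
  co <- suppressWarnings(summary(fit)$coefficients)
  list(slope = unname(co["a", "Estimate"]),
       slope_se = unname(co["a", "Std. Error"]),
       intercept = if (intercept == "free") {
         unname(stats::coef(fit)[1])
       } else 0)
}

#' Relative fluorescence quantum yield by the slope-ratio method
#'
#' `phi = phi_r * (m_F / m_r) * (n_F^2 / n_r^2)`, where `m_F` and `m_r`
#' are the dilution-series slopes of sample and reference, and `n_F`,
#' `n_r` the refractive indices of their solvents. The standard reference
#' is coumarin 153 in ethanol with `phi_r = 0.54`.
#'
#' @param m_F,m_r Sample and reference slopes, > 0.
#' @param n_F,n_r Refractive indices of sample and reference solvents.
#' @param phi_r Reference quantum yield, in (0, 1].
#' @return Object of class `lov_qy_result`: `phi`, `phi_r`,
#'   `slope_ratio`, `refractive_ratio_sq`.
#' @export
#' @examples
#' quantum_yield(m_F = 2000, m_r = 10000, n_F = 1.334, n_r = 1.361,
#'               phi_r = 0.54)
quantum_yield <- function(m_F, m_r, n_F, n_r, phi_r = 0.54) {
  if (m_F <= 0 || m_r <= 0) stop_validation("slopes must be positive")
  if (n_F <= 0 || n_r <= 0) stop_validation("refractive indices must be positive")
  if (phi_r <= 0 || phi_r > 1) stop_validation("phi_r must be in (0, 1]")
  phi <- phi_r * (m_F / m_r) * (n_F^2 / n_r^2)
  if (phi > 1) {
    warning("computed quantum yield exceeds 1; check slopes and reference")
  }
  structure(
    list(phi = phi, phi_r = phi_r, slope_ratio = m_F / m_r,
         refractive_ratio_sq = n_F^2 / n_r^2),
    class = "lov_qy_result"
  )
}

#' @export
print.lov_qy_result <- function(x, ...) {
  cat(sprintf(
    "<lov_qy_result> phi = %.4f (reference %.2f, slope ratio %.4f, n^2 ratio %.4f)\n",
    x$phi, x$phi_r, x$slope_ratio, x$refractive_ratio_sq))
  invisible(x)
}

#' A raw circular dichroism measurement
#'
#' @param ellipticity_mdeg Measured ellipticity in millidegrees.
#' @param concentration_M Protein concentration, mol per litre, > 0.
#' @param path_length_cm Cuvette path length, cm, > 0.
#' @param n_residues Number of residues of the construct, > 0 (the
#'   standard AsLOV2 construct, residues 404-546, has 143).
#' @return Object of class `lov_cd_measurement`.
#' @export
cd_measurement <- function(ellipticity_mdeg, concentration_M,
                           path_length_cm = 0.1, n_residues = 143L) {
  if (concentration_M <= 0) stop_validation("concentration must be positive")
  if (path_length_cm <= 0) stop_validation("path length must be positive")
  if (n_residues <= 0) stop_validation("n_residues must be positive")
  structure(
    list(ellipticity_mdeg = as.numeric(ellipticity_mdeg),
         concentration_M = concentration_M,
         path_length_cm = path_length_cm,
         n_residues = as.integer(n_residues)),
    class = "lov_cd_measurement"
  )
}

#' Convert measured ellipticity to mean residue ellipticity
#'
#' `[theta]_MRW = theta(mdeg) / (10 * c(M) * l(cm) * N_res)` in
#' deg cm^2 dmol^-1 -- the standard per-residue molar normalization of CD
#' signals. Homogeneous of degree -1 in concentration, path length and
#' residue count.
#'
#' @param measurement A [cd_measurement()].
#' @return Mean residue ellipticity, deg cm^2 dmol^-1 (vectorized over
#'   the stored ellipticities).
#' @export
#' @examples
#' mrw_ellipticity(cd_measurement(-17.16, 10e-6, 0.1, 143))
mrw_ellipticity <- function(measurement) {
  stopifnot(inherits(measurement, "lov_cd_measurement"))
  with(measurement,
       ellipticity_mdeg / (10 * concentration_M * path_length_cm * n_residues))
}

#' Fractional light-induced change in mean residue ellipticity
#'
#' `(dark - light) / dark`, sign-aware for the negative ellipticities of
#' alpha-helical minima: a positive value means the magnitude of the CD
#' signal shrinks under illumination (helix unfolding), 0 means no
#' response, 1 means complete loss.
#'
#' @param dark,light Mean residue ellipticities (deg cm^2 dmol^-1);
#'   `dark` must be nonzero.
#' @return Fractional change (dimensionless).
#' @export
cd_light_response <- function(dark, light) {
  if (any(dark == 0)) stop_validation("dark ellipticity must be nonzero")
  (dark - light) / dark
}
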
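#' Wavelength-resolved spectrum
#'
#' Container for a single spectrum: a strictly increasing wavelength grid in
#' nm and one signal value per wavelength. The `channel` records what the
#' signal is: absorbance (AU), fluorescence (arbitrary counts), or circular
#' dichroism (mdeg).
#'
#' @param wavelengths Numeric vector, nm, strictly increasing.
#' @param values Numeric vector, same length as `wavelengths`, no NA.
#' @param channel One of `"absorbance"`, `"fluorescence"`, `"cd"`.
#' @param label Free-text label.
#' @return Object of class `lov_spectrum`.
#' @export
#' @examples
#' s <- spectrum(400:500, dnorm(400:500, 450, 10), channel = "absorbance")
#' s
spectrum <- function(wavelengths, values,
                     channel = c("absorbance", "fluorescence", "cd"),
                     label = "") {
  channel <- match.arg(channel)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop_validation("wavelengths and values must have equal length")
  }
  if (anyNA(wavelengths) || anyNA(values)) {
    stop_validation("spectrum contains missing values")
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop_validation("wavelengths not strictly increasing")
  }
  structure(
    list(wavelengths = wavelengths, values = values,
         channel = channel, label = label),
    class = "lov_spectrum"
  )
}

#' @export
print.lov_spectrum <- function(x, ...) {
  cat(sprintf("<lov_spectrum> %s, %d points, %.1f-%.1f nm%s\n",
              x$channel, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Interpolate a spectrum at one wavelength
#'
#' @param x A `lov_spectrum`.
#' @param wavelength Wavelength in nm, inside the grid.
#' @return Linearly interpolated signal value.
#' @export
spectrum_at <- function(x, wavelength) {
  stopifnot(inherits(x, "lov_spectrum"))
  if (wavelength < min(x$wavelengths) || wavelength > max(x$wavelengths)) {
    stop_validation("wavelength outside spectrum grid")
  }
  stats::approx(x$wavelengths, x$values, xout = wavelength)$y
}

#' Time series of spectra from one experiment
#'
#' A sequence of spectra sharing one wavelength grid, recorded at strictly
#' increasing times (seconds internally; minute-resolved files are converted
#' on read). Used for titration time courses and spectrally resolved
#' photocycle experiments.
#'
#' @param times Numeric vector, seconds, strictly increasing.
#' @param spectra List of `lov_spectrum`, one per time, on a common grid.
#' @param temperature Absolute temperature in kelvin.
#' @return Object of class `lov_spectral_timeseries`.
#' @export
spectral_timeseries <- function(times, spectra, temperature = 295.15) {
  times <- as.numeric(times)
  if (length(times) != length(spectra)) {
    stop_validation("times and spectra must have equal length")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop_validation("times not strictly increasing")
  }
  if (!all(vapply(spectra, inherits, logical(1), "lov_spectrum"))) {
    stop_validation("spectra must all be lov_spectrum objects")
  }
  grid <- spectra[[1]]$wavelengths
  same <- vapply(spectra, function(s) {
    length(s$wavelengths) == length(grid) && all(s$wavelengths == grid)
  }, logical(1))
  if (!all(same)) {
    stop_validation("all spectra must share one wavelength grid")
  }
  if (!is.numeric(temperature) || temperature <= 0) {
    stop_validation("temperature must be positive (kelvin)")
  }
  structure(
    list(times = times, spectra = spectra, temperature = temperature),
    class = "lov_spectral_timeseries"
  )
}

#' @export
print.lov_spectral_timeseries <- function(x, ...) {
  cat(sprintf(
    "<lov_spectral_timeseries> %d timepoints over %.0f s, %d-point grid, %.2f K\n",
    length(x$times), diff(range(x$times)),
    length(x$spectra[[1]]$wavelengths), x$temperature))
  invisible(x)
}

#' Signal matrix of a spectral time series
#'
#' @param x A `lov_spectral_timeseries`.
#' @return Matrix, wavelengths in rows, timepoints in columns.
#' @export
as_matrix <- function(x) {
  stopifnot(inherits(x, "lov_spectral_timeseries"))
  m <- vapply(x$spectra, function(s) s$values,
              numeric(length(x$spectra[[1]]$wavelengths)))
  matrix(m, ncol = length(x$times),
         dimnames = list(NULL, as.character(x$times)))
}

#' Single-channel kinetic trace
#'
#' A scalar signal over time: typically absorbance at 450 nm for photocycle
#' kinetics, or mean residue ellipticity at 208 nm for CD-monitored
#' recovery. `illumination_intensity` is 0 for dark traces and the incident
#' blue-light power density (mW cm^-2) otherwise.
#'
#' @param times Numeric, seconds, strictly increasing.
#' @param signal Numeric, same length.
#' @param temperature Kelvin, > 0.
#' @param illumination_intensity mW cm^-2, >= 0 (0 = dark).
#' @return Object of class `lov_trace`.
#' @export
kinetic_trace <- function(times, signal, temperature = 295.15,
                          illumination_intensity = 0) {
  times <- as.numeric(times)
  signal <- as.numeric(signal)
  if (length(times) != length(signal)) {
    stop_validation("times and signal must have equal length")
  }
  if (anyNA(times) || anyNA(signal)) {
    stop_validation("trace contains missing values")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop_validation("times not strictly increasing")
  }
  if (!is.numeric(temperature) || temperature <= 0) {
    stop_validation("temperature must be positive (kelvin)")
  }
  if (illumination_intensity < 0) {
    stop_validation("illumination_intensity must be >= 0")
  }
  structure(
    list(times = times, signal = signal, temperature = temperature,
         illumination_intensity = illumination_intensity),
    class = "lov_trace"
  )
}

#' @export
print.lov_trace <- function(x, ...) {
  cat(sprintf(
    "<lov_trace> %d points over %.1f s, %.2f K, %s\n",
    length(x$times), diff(range(x$times)), x$temperature,
    if (x$illumination_intensity > 0) {
      sprintf("illuminated (%.1f mW cm-2)", x$illumination_intensity)
    } else "dark"))
  invisible(x)
}

#' Analysis configuration
#'
#' Shared run configuration: default temperature, the electron number z of
#' the redox couples, the indicator midpoint potential, the fraction window
#' guarding the log terms of the Nernst correlation, and the slope bounds of
#' the equilibration quality control.
#'
#' Defaults reflect the standard measurement conditions: 22 degrees C,
#' two-electron reduction for both the flavin analyte and the
#' phenosafranine indicator (midpoint -252 mV vs NHE), fraction window
#' (0.05, 0.95), and slope QC bounds (0.8, 1.2) -- correlations with slopes
#' outside this interval indicate insufficient redox equilibration and are
#' flagged as failing QC.
#'
#' @param temperature_default Kelvin.
#' @param z Electron number, 1 or 2.
#' @param indicator_midpoint_mv Indicator midpoint potential, mV vs NHE.
#' @param fraction_window Length-2 numeric in (0,1), low < high.
#' @param slope_qc Length-2 numeric bounds on the correlation slope.
#' @param random_seed Integer seed used by simulators when none is given.
#' @param fit_tol Relative convergence tolerance for nonlinear fits.
#' @return Object of class `lov_config` (a validated list).
#' @export
analysis_config <- function(temperature_default = 295.15,
                            z = 2L,
                            indicator_midpoint_mv = -252,
                            fraction_window = c(0.05, 0.95),
                            slope_qc = c(0.8, 1.2),
                            random_seed = 1L,
                            fit_tol = 1e-10) {
  if (!z %in% c(1L, 2L)) stop_validation("z must be 1 or 2")
  if (length(fraction_window) != 2 ||
      fraction_window[1] >= fraction_window[2] ||
      any(fraction_window <= 0) || any(fraction_window >= 1)) {
    stop_validation("fraction_window must be (low, high) within (0,1)")
  }
  if (length(slope_qc) != 2 || slope_qc[1] >= slope_qc[2]) {
    stop_validation("slope_qc must be (low, high) with low < high")
  }
  if (temperature_default <= 0) {
    stop_validation("temperature_default must be positive")
  }
  structure(
    list(temperature_default = temperature_default, z = as.integer(z),
         indicator_midpoint_mv = indicator_midpoint_mv,
         fraction_window = fraction_window, slope_qc = slope_qc,
         random_seed = as.integer(random_seed), fit_tol = fit_tol),
    class = "lov_config"
  )
}

#' Per-timepoint oxidized/reduced fractions of one redox species
#'
#' @param times Numeric, seconds, strictly increasing.
#' @param f_ox,f_red Numeric in \[0,1\], `f_ox + f_red = 1` at each timepoint.
#' @param species `"analyte"` or `"indicator"`.
#' @return Object of class `lov_fraction_series`.
#' @export
fraction_series <- function(times, f_ox, f_red,
                            species = c("analyte", "indicator")) {
  species <- match.arg(species)
  times <- as.numeric(times)
  f_ox <- as.numeric(f_ox)
  f_red <- as.numeric(f_red)
  n <- length(times)
  if (length(f_ox) != n || length(f_red) != n) {
    stop_validation("times, f_ox, f_red must have equal length")
  }
  if (any(f_ox < -1e-9) || any(f_ox > 1 + 1e-9) ||
      any(f_red < -1e-9) || any(f_red > 1 + 1e-9)) {
    stop_validation("fractions must lie in [0, 1]")
  }
  if (any(abs(f_ox + f_red - 1) > 1e-9)) {
    stop_validation("f_ox + f_red must equal 1 at every timepoint")
  }
  structure(
    list(times = times, f_ox = pmin(pmax(f_ox, 0), 1),
         f_red = pmin(pmax(f_red, 0), 1), species = species),
    class = "lov_fraction_series"
  )
}

#' @export
print.lov_fraction_series <- function(x, ...) {
  cat(sprintf("<lov_fraction_series> %s, %d timepoints, f_red %.3f -> %.3f\n",
              x$species, length(x$times),
              x$f_red[1], x$f_red[length(x$f_red)]))
  invisible(x)
}

# Typed conditions: validation errors (bad values in a structurally sound
# input) vs format errors (malformed file), so callers can distinguish.
stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("lov_validation_error", "error")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("lov_format_error", "error")))
}
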
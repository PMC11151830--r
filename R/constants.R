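#' Physical constants used in Nernst and Arrhenius arithmetic
#'
#' CODATA values for the molar gas constant (J mol^-1 K^-1) and the Faraday
#' constant (C mol^-1). Potentials are carried in millivolts versus the
#' normal hydrogen electrode (NHE) throughout the package; conversion to
#' volts happens only inside Nernst arithmetic.
#'
#' @name lov_constants
#' @keywords internal
NULL

GAS_CONSTANT <- 8.314462618   # J mol^-1 K^-1
FARADAY <- 96485.332          # C mol^-1

#' Nernst slope RT/zF in millivolts
#'
#' The natural-log Nernst slope for a z-electron couple at temperature `T`,
#' expressed in mV so it can be combined directly with potentials in mV.
#' At 295.15 K and z = 2 this is 12.717 mV.
#'
#' @param z Number of transferred electrons (1 or 2).
#' @param temperature Absolute temperature in kelvin.
#' @return Slope in mV (numeric scalar).
#' @export
#' @examples
#' nernst_slope_mv(z = 2, temperature = 295.15)
nernst_slope_mv <- function(z, temperature) {
  stopifnot(z %in% c(1L, 2L), temperature > 0)
  1000 * GAS_CONSTANT * temperature / (z * FARADAY)
}
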
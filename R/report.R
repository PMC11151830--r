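#' Published characterization values of AsLOV2 methionine variants
#'
#' Reference table of measured properties of wild-type AsLOV2 (residues
#' 404-546) and its eleven soluble methionine variants, all determined at
#' 22 degrees C: dark-recovery rate `k_rec` (s^-1), Arrhenius activation
#' energy `EA_kj_mol` (kJ mol^-1), photoactivation rate `k1` (s^-1, at
#' 3 mW cm^-2 blue light), mean residue ellipticity at 208 nm in the dark
#' and light states (`theta_mrw_dark`, `theta_mrw_light`, in units of
#' 10^3 deg cm^2 dmol^-1), fluorescence quantum yield `phi_f`, and flavin
#' reduction midpoint potential `E0_mv` (mV vs NHE). These serve as
#' ground-truth inputs for simulation-based validation and for derived
#' summary statistics.
#'
#' @return data.frame, one row per variant, wild type first.
#' @export
aslov2_variants <- function() {
  df <- read.table(header = TRUE, text = "
variant      k_rec  EA_kj_mol  k1     theta_mrw_dark theta_mrw_light phi_f  E0_mv
Wild_type    0.013  61.0       0.048  -12.0          -9.0            0.09   -278
I427M        0.050  70.5       0.018  -13.5          -11.9           0.10   -260
F434M        0.024  43.8       0.021  -12.7          -10.2           0.08   -258
L437M        0.011  59.5       0.027  -13.4          -9.4            0.08   -263
L453M        0.047  61.4       0.032  -12.4          -10.2           0.09   -268
V463M        0.014  84.3       0.016  -9.9           -9.1            0.09   -236
I466M        0.012  64.7       0.039  -13.5          -10.5           0.07   -257
L480M        0.020  32.9       0.026  -10.7          -10.3           0.04   -270
F494M        0.003  70.4       0.013  -12.1          -10.5           0.04   -268
L496M        0.018  63.8       0.028  -10.8          -7.1            0.08   -279
Q513M        0.002  62.9       0.005  -14.1          -13.1           0.04   -252
I466M:L496M  0.019  65.0       0.019  -12.8          -10.3           0.07   -263
")
  df$variant <- sub("_", " ", df$variant)
  df
}

#' Published reduction midpoint potentials of NcVVD variants
#'
#' Flavin reduction midpoint potentials (mV vs NHE, 22 degrees C) of the
#' Neurospora crassa Vivid photoreceptor (residues 37-186) and its
#' methionine/cysteine replacement variants.
#'
#' @return data.frame with columns `variant` and `E0_mv`.
#' @export
ncvvd_variants <- function() {
  df <- read.table(header = TRUE, text = "
variant                E0_mv
Wild_type              -241
M135I                  -242
M165I                  -247
M135I:M165I            -243
C108A:M135I:M165I      -264
")
  df$variant <- sub("_", " ", df$variant)
  df
}

#' Assemble a per-variant characterization record
#'
#' One row of the report: every field is optional (NA when not measured)
#' and carries a provenance tag (`"fitted"` when produced by this
#' pipeline, `"supplied"` for externally provided values).
#'
#' @param variant Variant name (unique within a report).
#' @param k_rec,EA_kj_mol,k1,theta_mrw_dark,theta_mrw_light,phi_f,E0_mv
#'   Measured quantities; see [aslov2_variants()] for units.
#' @param provenance Single tag or named character vector per field.
#' @return Object of class `lov_variant_record` (a one-row data.frame
#'   plus provenance attribute).
#' @export
variant_record <- function(variant, k_rec = NA, EA_kj_mol = NA, k1 = NA,
                           theta_mrw_dark = NA, theta_mrw_light = NA,
                           phi_f = NA, E0_mv = NA,
                           provenance = "supplied") {
  rec <- data.frame(variant = variant, k_rec = k_rec,
                    EA_kj_mol = EA_kj_mol, k1 = k1,
                    theta_mrw_dark = theta_mrw_dark,
                    theta_mrw_light = theta_mrw_light,
                    phi_f = phi_f, E0_mv = E0_mv)
  attr(rec, "provenance") <- provenance
  class(rec) <- c("lov_variant_record", class(rec))
  rec
}

#' Build a variant summary report
#'
#' Assembles the per-variant characterization table plus derived rows
#' relative to the designated wild type: midpoint shift `delta_E0`
#' (variant minus wild type, mV), its mean and maximum, the dark-recovery
#' fold change (`k_rec / k_rec(wild type)`; values > 1 are faster,
#' < 1 slower recovery), the CD light response, and the
#' photostationary-state dark fraction where both rates are available.
#' Display rounding follows the conventions of the field: rates to three
#' decimals, midpoints to integer mV, activation energies to one decimal.
#'
#' @param records data.frame of variant records (e.g. [aslov2_variants()]
#'   or rbind-ed [variant_record()] rows).
#' @param wild_type Name of the wild-type row.
#' @return Object of class `lov_report`: `table` (per-variant, with
#'   derived columns) and `summary` (mean/max midpoint shift).
#' @export
#' @examples
#' rep <- build_report(aslov2_variants(), wild_type = "Wild type")
#' rep$summary$mean_delta_E0
build_report <- function(records, wild_type) {
  records <- as.data.frame(records)
  if (anyDuplicated(records$variant)) {
    stop_validation("variant names must be unique")
  }
  wt <- records[records$variant == wild_type, ]
  if (nrow(wt) != 1) {
    stop_validation(sprintf("wild type '%s' not found", wild_type))
  }
  others <- records[records$variant != wild_type, , drop = FALSE]
  tab <- records
  tab$delta_E0_mv <- tab$E0_mv - wt$E0_mv
  tab$recovery_fold_change <- tab$k_rec / wt$k_rec
  tab$cd_light_response <- ifelse(
    !is.na(tab$theta_mrw_dark) & tab$theta_mrw_dark != 0,
    (tab$theta_mrw_dark - tab$theta_mrw_light) / tab$theta_mrw_dark,
    NA_real_)
  tab$pss_dark_fraction <- ifelse(
    !is.na(tab$k1) & !is.na(tab$k_rec),
    tab$k_rec / (tab$k1 + tab$k_rec), NA_real_)
  summary <- if (nrow(others) > 0 && any(!is.na(others$E0_mv))) {
    sh <- summarize_midpoint_shifts(wt$E0_mv,
                                    stats::setNames(others$E0_mv,
                                                    others$variant))
    list(mean_delta_E0 = sh$mean_delta_E0,
         mean_delta_E0_display = round(sh$mean_delta_E0),
         max_delta_E0 = sh$max_delta_E0)
  } else {
    list(mean_delta_E0 = NA_real_, mean_delta_E0_display = NA_real_,
         max_delta_E0 = NA_real_)
  }
  structure(list(table = tab, summary = summary, wild_type = wild_type),
            class = "lov_report")
}

#' @export
print.lov_report <- function(x, ...) {
  tab <- x$table
  disp <- data.frame(
    variant = tab$variant,
    k_rec = sprintf("%.3f", tab$k_rec),
    EA = sprintf("%.1f", tab$EA_kj_mol),
    k1 = sprintf("%.3f", tab$k1),
    phi_f = sprintf("%.2f", tab$phi_f),
    E0_mV = sprintf("%.0f", tab$E0_mv),
    dE0_mV = sprintf("%+.0f", tab$delta_E0_mv),
    rec_fold = sprintf("%.2f", tab$recovery_fold_change)
  )
  cat(sprintf("<lov_report> wild type: %s\n", x$wild_type))
  print(disp, row.names = FALSE)
  if (!is.na(x$summary$mean_delta_E0)) {
    cat(sprintf("mean midpoint shift: %+d mV (max %+.0f mV)\n",
                x$summary$mean_delta_E0_display, x$summary$max_delta_E0))
  }
  invisible(x)
}
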
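# Independent oracles used across tests.

# Brute-force grid search for the reduced fraction of a two-component
# mixture: spectrum = scale * (f_ox * ox + (1 - f_ox) * red) + noise.
# Scans f_ox on a fixed-resolution grid minimizing the residual sum of
# squares. Deliberately naive -- shares no code with unmix_fractions().
grid_unmix_oracle <- function(values, ox, red, scale, resolution = 1e-3) {
  f_grid <- seq(0, 1, by = resolution)
  rss <- vapply(f_grid, function(f) {
    sum((values - scale * (f * ox + (1 - f) * red))^2)
  }, numeric(1))
  f_grid[which.min(rss)]
}

# Closed-form two-point Arrhenius slope.
two_point_EA_kj <- function(T1, k1, T2, k2) {
  -8.314462618 * (log(k2) - log(k1)) / (1 / T2 - 1 / T1) / 1000
}

# Default phenosafranine/flavin study conditions shared by redox tests.
default_config <- function(...) analysis_config(...)

# Build a lov_alignment directly from named aligned strings (no file I/O).
make_alignment_for_test <- function(named) {
  mat <- do.call(rbind, strsplit(toupper(unname(named)), ""))
  rownames(mat) <- names(named)
  structure(list(ids = names(named), seqs = mat), class = "lov_alignment")
}

# LOV signature residues as fixture column spec for a 120-column alignment
# whose ungapped reference starts at residue 404 (position p -> column
# p - 403).
lov_sig_cols <- function() {
  spec <- aslov2_conserved_spec()
  stats::setNames(spec$residues, spec$positions - 403L)
}
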
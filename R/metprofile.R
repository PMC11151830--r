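#' Conserved-residue specification for filtering LOV-like sequences
#'
#' An ordered set of (reference position, expected residue) pairs and the
#' minimum number of matches a sequence must show at those positions to be
#' retained as a genuine LOV homolog.
#'
#' @param positions Integer vector of reference positions, strictly
#'   increasing.
#' @param residues Character vector of expected residues (single letters),
#'   same length.
#' @param min_matches Minimum matches for retention, <= number of
#'   positions.
#' @return Object of class `lov_conserved_spec`.
#' @export
conserved_spec <- function(positions, residues, min_matches) {
  positions <- as.integer(positions)
  residues <- toupper(as.character(residues))
  if (length(positions) != length(residues)) {
    stop_validation("positions and residues must have equal length")
  }
  if (length(positions) > 1 && any(diff(positions) <= 0)) {
    stop_validation("positions must be strictly increasing")
  }
  if (!all(residues %in% AA_ALPHABET)) {
    stop_validation("residues must be standard amino-acid letters")
  }
  if (min_matches > length(positions) || min_matches < 1) {
    stop_validation("min_matches must be between 1 and the number of positions")
  }
  structure(
    list(positions = positions, residues = residues,
         min_matches = as.integer(min_matches)),
    class = "lov_conserved_spec"
  )
}

#' The canonical AsLOV2 conserved-residue signature
#'
#' The ten signature residues of LOV photosensor domains in AsLOV2
#' numbering -- G447, N449, C450 (the adduct-forming cysteine), R451,
#' F452, L453, Q454, N482, N492, and Q513 (the signal-relaying
#' glutamine). By default a sequence must match at least 8 of the 10 to
#' pass the homolog filter.
#'
#' @param min_matches Retention threshold (default 8).
#' @return A [conserved_spec()].
#' @export
aslov2_conserved_spec <- function(min_matches = 8L) {
  conserved_spec(
    positions = c(447L, 449L, 450L, 451L, 452L, 453L, 454L, 482L, 492L, 513L),
    residues = c("G", "N", "C", "R", "F", "L", "Q", "N", "N", "Q"),
    min_matches = min_matches
  )
}

#' Map alignment columns to reference-sequence numbering
#'
#' Non-gap columns of the reference record are assigned consecutive
#' positions starting at `reference_numbering_start`; columns where the
#' reference has a gap (insert columns) map to NA.
#'
#' @param alignment A `lov_alignment` (see [read_alignment()]).
#' @param reference_id Identifier of the reference record.
#' @param reference_numbering_start First residue number of the reference
#'   (404 for the standard AsLOV2 construct).
#' @return Integer vector of length `ncol(alignment)`: reference position
#'   per column, NA for insert columns.
#' @export
map_columns_to_reference <- function(alignment, reference_id,
                                     reference_numbering_start = 404L) {
  stopifnot(inherits(alignment, "lov_alignment"))
  i <- match(reference_id, alignment$ids)
  if (is.na(i)) {
    stop_validation(sprintf("reference '%s' not found in alignment",
                            reference_id))
  }
  ref <- alignment$seqs[i, ]
  nongap <- ref != "-"
  if (!any(nongap)) stop_validation("reference sequence is all gaps")
  map <- rep(NA_integer_, length(ref))
  map[nongap] <- seq.int(reference_numbering_start,
                         length.out = sum(nongap))
  map
}

#' Filter an alignment by conserved signature residues
#'
#' A sequence is retained iff its residues at the mapped signature columns
#' match the expected residue at `min_matches` or more positions. Matching
#' is case-insensitive (the alignment is upcased on read); gaps count as
#' mismatches. Filtering is idempotent.
#'
#' @param alignment A `lov_alignment`.
#' @param spec A [conserved_spec()].
#' @param column_map Column-to-position map from
#'   [map_columns_to_reference()].
#' @return List with `alignment` (retained sub-alignment) and
#'   `match_counts` (named integer vector, matches per input sequence).
#' @export
conserved_residue_filter <- function(alignment, spec, column_map) {
  stopifnot(inherits(alignment, "lov_alignment"),
            inherits(spec, "lov_conserved_spec"))
  cols <- match(spec$positions, column_map)
  if (anyNA(cols)) {
    stop_validation(sprintf(
      "conserved positions not present in column map: %s",
      paste(spec$positions[is.na(cols)], collapse = ", ")))
  }
  sub <- alignment$seqs[, cols, drop = FALSE]
  matches <- sub == matrix(rep(spec$residues, each = nrow(sub)),
                           nrow = nrow(sub))
  counts <- rowSums(matches)
  keep <- counts >= spec$min_matches
  names(counts) <- alignment$ids
  list(
    alignment = structure(
      list(ids = alignment$ids[keep],
           seqs = alignment$seqs[keep, , drop = FALSE]),
      class = "lov_alignment"),
    match_counts = counts
  )
}

#' Per-column methionine frequency profile of an alignment
#'
#' For every alignment column: the number of non-gap residues, the number
#' of methionines, and the methionine frequency over non-gap residues
#' (gaps are excluded from the denominator; all-gap columns get frequency
#' 0 and are flagged). Columns are keyed by reference numbering where the
#' column map provides one.
#'
#' @param alignment A `lov_alignment`.
#' @param column_map Optional map from [map_columns_to_reference()].
#' @return data.frame with columns `alignment_column`, `reference_position`,
#'   `n_nongap`, `n_met`, `met_frequency`, `all_gap`.
#' @export
met_frequency_profile <- function(alignment, column_map = NULL) {
  stopifnot(inherits(alignment, "lov_alignment"))
  if (nrow(alignment$seqs) == 0) stop_validation("alignment is empty")
  ncols <- ncol(alignment$seqs)
  if (is.null(column_map)) column_map <- rep(NA_integer_, ncols)
  if (length(column_map) != ncols) {
    stop_validation("column_map length must equal alignment width")
  }
  n_nongap <- colSums(alignment$seqs != "-")
  n_met <- colSums(alignment$seqs == "M")
  freq <- ifelse(n_nongap > 0, n_met / n_nongap, 0)
  data.frame(
    alignment_column = seq_len(ncols),
    reference_position = as.integer(column_map),
    n_nongap = as.integer(n_nongap),
    n_met = as.integer(n_met),
    met_frequency = freq,
    all_gap = n_nongap == 0
  )
}

#' Write a methionine-frequency profile as TSV
#'
#' @param profile Output of [met_frequency_profile()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_met_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
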
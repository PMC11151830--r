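#' @importFrom utils read.table write.table
NULL

# '#'-prefixed "key: value" metadata header lines at the top of a file.
read_metadata_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines)
  hdr <- hdr[hdr == seq_along(hdr)]  # only the leading block
  meta <- list()
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  list(meta = meta, n_skip = length(hdr))
}

sniff_sep <- function(path, n_skip) {
  first <- readLines(path, n = n_skip + 1L, warn = FALSE)[n_skip + 1L]
  if (grepl("\t", first)) "\t" else ","
}

meta_num <- function(meta, key) {
  if (is.null(meta[[key]])) NULL else as.numeric(meta[[key]])
}

#' Read a spectral time series from CSV/TSV
#'
#' Two dialects are supported. `wide` (canonical, written by
#' [write_spectral_timeseries()]): first column is the wavelength in nm,
#' each remaining column is one timepoint with the time as its numeric
#' header. `long`: three columns `time`, `wavelength`, `value`. The
#' delimiter (comma or tab) is sniffed. Leading `# key: value` lines carry
#' metadata; recognized keys are `temperature_k`, `time_unit` (`s` or
#' `min`; minutes are converted to seconds on read) and `channel`.
#'
#' @param path File path.
#' @param dialect `"wide"` or `"long"`.
#' @param config [analysis_config()] supplying defaults for metadata that
#'   the file does not carry.
#' @return A [spectral_timeseries()].
#' @export
read_spectral_timeseries <- function(path, dialect = c("wide", "long"),
                                     config = analysis_config()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format(paste("file not found:", path))
  h <- read_metadata_header(path)
  sep <- sniff_sep(path, h$n_skip)
  df <- read.table(path, header = TRUE, sep = sep, skip = h$n_skip,
                   check.names = FALSE, comment.char = "")
  temperature <- meta_num(h$meta, "temperature_k")
  if (is.null(temperature)) temperature <- config$temperature_default
  tscale <- if (identical(h$meta$time_unit, "min")) 60 else 1
  channel <- h$meta$channel
  if (is.null(channel)) channel <- "absorbance"

  if (dialect == "wide") {
    wl <- as.numeric(df[[1]])
    if (anyNA(wl)) stop_format("non-numeric wavelength cell in first column")
    dup <- which(duplicated(wl))
    if (length(dup)) {
      stop_format(sprintf("duplicate wavelength at row %d (%g nm)",
                          dup[1], wl[dup[1]]))
    }
    if (length(wl) > 1 && any(diff(wl) <= 0)) {
      stop_validation("wavelengths not strictly increasing")
    }
    times <- suppressWarnings(as.numeric(names(df)[-1]))
    if (anyNA(times)) stop_format("timepoint column headers must be numeric")
    spectra <- lapply(seq_along(times) + 1L, function(j) {
      v <- as.numeric(df[[j]])
      if (anyNA(v)) stop_format(sprintf("non-numeric value in column %d", j))
      spectrum(wl, v, channel = channel)
    })
    spectral_timeseries(times * tscale, spectra, temperature = temperature)
  } else {
    need <- c("time", "wavelength", "value")
    if (!all(need %in% names(df))) {
      stop_format("long dialect needs columns time, wavelength, value")
    }
    times <- sort(unique(df$time))
    spectra <- lapply(times, function(tt) {
      sub <- df[df$time == tt, , drop = FALSE]
      sub <- sub[order(sub$wavelength), , drop = FALSE]
      dup <- which(duplicated(sub$wavelength))
      if (length(dup)) {
        stop_format(sprintf(
          "duplicate wavelength %g nm at time %g", sub$wavelength[dup[1]], tt))
      }
      spectrum(sub$wavelength, sub$value, channel = channel)
    })
    spectral_timeseries(times * tscale, spectra, temperature = temperature)
  }
}

#' Write a spectral time series as wide CSV
#'
#' Canonical on-disk format: `# key: value` metadata lines, then a header
#' row `wavelength_nm, <t1>, <t2>, ...` and one row per wavelength. Times
#' are written in seconds. Round-trips losslessly through
#' [read_spectral_timeseries()].
#'
#' @param x A [spectral_timeseries()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectral_timeseries <- function(x, path) {
  stopifnot(inherits(x, "lov_spectral_timeseries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature_k: %.17g", x$temperature), con)
  writeLines("# time_unit: s", con)
  writeLines(sprintf("# channel: %s", x$spectra[[1]]$channel), con)
  m <- as_matrix(x)
  df <- data.frame(wavelength_nm = x$spectra[[1]]$wavelengths, m,
                   check.names = FALSE)
  names(df) <- c("wavelength_nm", sprintf("%.17g", x$times))
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a kinetic trace from a two-column table
#'
#' Expects columns `time` (seconds) and `signal`, with optional leading
#' `# key: value` metadata lines. Recognized keys: `temperature_k`,
#' `temperature_c`, `intensity_mw_cm2`. Missing metadata is filled from
#' `config` (temperature) or defaults to dark (intensity 0). At least four
#' points are required, since no exponential fit is possible below that.
#'
#' @param path File path.
#' @param config [analysis_config()] for defaults.
#' @return A [kinetic_trace()].
#' @export
read_trace <- function(path, config = analysis_config()) {
  if (!file.exists(path)) stop_format(paste("file not found:", path))
  h <- read_metadata_header(path)
  sep <- sniff_sep(path, h$n_skip)
  raw <- read.table(path, header = TRUE, sep = sep, skip = h$n_skip,
                    check.names = FALSE, comment.char = "",
                    colClasses = "character")
  if (ncol(raw) < 2) stop_format("trace file needs columns time, signal")
  tt <- suppressWarnings(as.numeric(raw[[1]]))
  ss <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(tt) | is.na(ss))
  if (length(bad)) {
    stop_format(sprintf("non-numeric cell at data line %d", bad[1]))
  }
  if (length(tt) < 4) {
    stop_validation("insufficient points: need >= 4 for an exponential fit")
  }
  temperature <- meta_num(h$meta, "temperature_k")
  if (is.null(temperature)) {
    tc <- meta_num(h$meta, "temperature_c")
    temperature <- if (!is.null(tc)) tc + 273.15 else config$temperature_default
  }
  intensity <- meta_num(h$meta, "intensity_mw_cm2")
  if (is.null(intensity)) intensity <- 0
  kinetic_trace(tt, ss, temperature = temperature,
                illumination_intensity = intensity)
}

#' Write a kinetic trace
#'
#' @param x A [kinetic_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "lov_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature_k: %.17g", x$temperature), con)
  writeLines(sprintf("# intensity_mw_cm2: %.17g", x$illumination_intensity), con)
  df <- data.frame(time = sprintf("%.17g", x$times),
                   signal = sprintf("%.17g", x$signal))
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read a protein multiple sequence alignment from aligned FASTA
#'
#' All records must have the same aligned length; the alphabet is the 20
#' standard amino acids plus the gap character `-`. Lowercase residues are
#' upcased on read; any other character is rejected.
#'
#' @param path Aligned FASTA file.
#' @return Object of class `lov_alignment`: a list with `ids` (record
#'   identifiers) and `seqs` (character matrix, sequences in rows, aligned
#'   columns in columns).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop_format(paste("file not found:", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop_format("empty alignment file")
  chars <- toupper(as.character(set))
  lens <- nchar(chars)
  if (length(unique(lens)) > 1) {
    off <- names(set)[lens != lens[1]]
    stop_validation(paste("unequal aligned lengths in records:",
                          paste(off, collapse = ", ")))
  }
  make_alignment(names(set), chars)
}

make_alignment <- function(ids, seq_strings) {
  mat <- do.call(rbind, strsplit(toupper(seq_strings), ""))
  bad <- !(mat %in% c(AA_ALPHABET, "-"))
  if (any(bad)) {
    stop_validation(sprintf(
      "invalid characters in alignment: %s",
      paste(unique(mat[bad]), collapse = " ")))
  }
  rownames(mat) <- ids
  structure(list(ids = ids, seqs = mat), class = "lov_alignment")
}

#' @export
print.lov_alignment <- function(x, ...) {
  cat(sprintf("<lov_alignment> %d sequences x %d columns\n",
              nrow(x$seqs), ncol(x$seqs)))
  invisible(x)
}

#' Write an alignment as aligned FASTA
#'
#' @param x A `lov_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  stopifnot(inherits(x, "lov_alignment"))
  set <- Biostrings::BStringSet(apply(x$seqs, 1, paste0, collapse = ""))
  names(set) <- x$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an analysis configuration from YAML
#'
#' Keys mirror the arguments of [analysis_config()]; unknown keys are an
#' error, missing keys fall back to the defaults.
#'
#' @param path YAML file.
#' @return A `lov_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_format(paste("file not found:", path))
  y <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop_format(paste("unknown config keys:", paste(bad, collapse = ", ")))
  }
  do.call(analysis_config, y)
}

#' Emit a progress/diagnostic message to stderr
#'
#' Verbosity is controlled by `options(lovredox.verbose = TRUE/FALSE)`
#' (default off).
#' @param ... Passed to [sprintf()].
#' @keywords internal
lov_log <- function(...) {
  if (isTRUE(getOption("lovredox.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}
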
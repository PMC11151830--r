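test_that("spectrum and trace constructors enforce their invariants", {
  expect_s3_class(spectrum(1:3, c(0.1, 0.2, 0.3)), "lov_spectrum")
  expect_error(spectrum(c(450, 449, 451), 1:3),
               "not strictly increasing", class = "lov_validation_error")
  expect_error(spectrum(1:3, 1:2), "equal length",
               class = "lov_validation_error")
  expect_error(spectrum(1:3, c(1, NA, 3)), "missing",
               class = "lov_validation_error")
  expect_error(kinetic_trace(c(0, 1, 1), 1:3), "strictly increasing",
               class = "lov_validation_error")
  expect_error(kinetic_trace(0:2, 1:3, temperature = -1), "temperature",
               class = "lov_validation_error")
  expect_error(
    spectral_timeseries(c(0, 10), list(spectrum(1:3, 1:3),
                                       spectrum(2:4, 1:3))),
    "share one wavelength grid", class = "lov_validation_error")
})

test_that("wide spectral files parse, round-trip bitwise, and reject bad grids", {
  grid <- seq(440, 442)
  sts <- spectral_timeseries(
    c(0, 60), list(spectrum(grid, c(0.11, 0.22, 0.33)),
                   spectrum(grid, c(0.10, 0.20, 0.30))),
    temperature = 298.65)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectral_timeseries(sts, path)
  back <- read_spectral_timeseries(path, "wide")
  expect_identical(back$times, sts$times)
  expect_identical(back$temperature, sts$temperature)
  expect_identical(as_matrix(back), as_matrix(sts))
  expect_equal(length(back$spectra), 2)
  expect_equal(length(back$spectra[[1]]$wavelengths), 3)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,0,60", "450,1,1", "449,1,1", "451,1,1"), bad)
  expect_error(read_spectral_timeseries(bad, "wide"),
               "not strictly increasing", class = "lov_validation_error")
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,0", "450,1", "450,1"), dup)
  expect_error(read_spectral_timeseries(dup, "wide"),
               "duplicate wavelength", class = "lov_format_error")
})

test_that("long dialect and minute-resolved files are read correctly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# time_unit: min", "time,wavelength,value",
               "0,450,0.5", "0,451,0.6", "5,450,0.4", "5,451,0.5"), path)
  sts <- read_spectral_timeseries(path, "long")
  expect_equal(sts$times, c(0, 300))  # minutes converted to seconds
  expect_equal(sts$spectra[[2]]$values, c(0.4, 0.5))
})

test_that("trace reader fills defaults, honors metadata, rejects short/bad files", {
  path <- withr::local_tempfile(fileext = ".csv")
  tt <- seq(0, 90, by = 10)
  writeLines(c("time,signal", paste(tt, 0.4 - 0.3 * exp(-0.02 * tt),
                                    sep = ",")), path)
  tr <- read_trace(path)
  expect_equal(tr$temperature, 295.15)  # default: 22 degrees C
  expect_equal(tr$illumination_intensity, 0)

  lit <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# intensity_mw_cm2: 3", "# temperature_c: 30",
               "time,signal", paste(tt, 0.1 * tt, sep = ",")), lit)
  tr2 <- read_trace(lit)
  expect_equal(tr2$illumination_intensity, 3)
  expect_equal(tr2$temperature, 303.15)

  short <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,signal", "0,1", "1,2", "2,3"), short)
  expect_error(read_trace(short), "insufficient points",
               class = "lov_validation_error")

  nonnum <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,signal", "0,1", "1,x", "2,3", "3,4"), nonnum)
  expect_error(read_trace(nonnum), "line 2", class = "lov_format_error")
})

test_that("trace round-trip is lossless", {
  tr <- kinetic_trace(c(0, 1.5, 3, 7), c(0.1, 0.2, 0.25, 0.3),
                      temperature = 301.4, illumination_intensity = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_identical(back$times, tr$times)
  expect_identical(back$signal, tr$signal)
  expect_identical(back$temperature, tr$temperature)
  expect_identical(back$illumination_intensity, tr$illumination_intensity)
})

test_that("aligned FASTA reading validates, upcases, and round-trips", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEF", ">b", "acd-f"), path)
  aln <- read_alignment(path)
  expect_equal(dim(aln$seqs), c(2L, 5L))
  expect_equal(unname(aln$seqs[2, ]), c("A", "C", "D", "-", "F"))

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEF", ">b", "ACDEFG"), ragged)
  expect_error(read_alignment(ragged), "unequal aligned lengths.*b",
               class = "lov_validation_error")

  badchar <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC2EF"), badchar)
  expect_error(read_alignment(badchar), "invalid characters",
               class = "lov_validation_error")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_alignment(empty), "empty", class = "lov_format_error")

  out <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, out)
  expect_identical(read_alignment(out)$seqs, aln$seqs)
})

test_that("random valid inputs round-trip losslessly through all writers", {
  set.seed(42)
  for (rep in 1:3) {
    grid <- sort(sample(300:700, 25))
    times <- sort(sample(0:5000, 8))
    sts <- spectral_timeseries(
      times, lapply(1:8, function(i) spectrum(grid, runif(25))),
      temperature = runif(1, 280, 320))
    p <- withr::local_tempfile(fileext = ".csv")
    write_spectral_timeseries(sts, p)
    back <- read_spectral_timeseries(p, "wide")
    expect_identical(as_matrix(back), as_matrix(sts))
    expect_identical(back$times, sts$times)
  }
})

test_that("YAML config round-trips and unknown keys are rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("indicator_midpoint_mv: -252", "z: 2",
               "fraction_window: [0.05, 0.95]"), path)
  cfg <- read_analysis_config(path)
  expect_equal(cfg$indicator_midpoint_mv, -252)
  expect_equal(cfg$slope_qc, c(0.8, 1.2))

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("indicator_mid: -252", bad)
  expect_error(read_analysis_config(bad), "unknown config keys",
               class = "lov_format_error")
})
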
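Package: lovredox
Title: Redox Titration and Photocycle Analysis of LOV Photoreceptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative characterization of light-oxygen-voltage (LOV)
    photoreceptor domains from spectroscopic data. Estimates flavin
    reduction midpoint potentials from dye-coupled chemical-reduction
    titrations by spectral unmixing and Nernst correlation against a redox
    indicator, fits the two-state photocycle model (dark recovery,
    photoactivation under constant illumination, Arrhenius temperature
    dependence), computes relative fluorescence quantum yields by the
    slope-ratio method, converts circular dichroism signals to mean
    residue ellipticity, and profiles per-position methionine frequencies
    in LOV multiple sequence alignments. A synthetic-data module generates
    every input the pipeline consumes so that all stages can be validated
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
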
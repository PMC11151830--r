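# lovredox

Quantitative analysis of light–oxygen–voltage (LOV) photoreceptor
characterization data, built around the AsLOV2 model system (the second
LOV domain of *Avena sativa* phototropin 1) and its methionine variants.

LOV domains bind a flavin chromophore whose blue-light response — and
whose chemical two-electron reduction to the hydroquinone — both hinge on
flavin redox chemistry. This package implements the full measurement
pipeline with which such domains are characterized:

* **Reduction midpoint potentials** from dye-coupled chemical-reduction
  titrations. The solution potential *E* is read off a redox indicator of
  known midpoint (phenosafranine, *E*ᵣ₀ = −252 mV vs NHE) while the
  analyte's oxidized/reduced fractions are followed spectroscopically.
  Equating the two Nernst relations,

  *E*₀ − *E*ᵣ₀ = (RT/zF) · [ln(f_red/f_ox) − ln(f_r,red/f_r,ox)],

  so a linear correlation of the two log terms has unit slope and its
  axis offset is the midpoint difference. Fractions are obtained by
  non-negative least-squares unmixing of every spectrum against reference
  spectra of the four species; correlations with slope outside [0.8, 1.2]
  fail the redox-equilibration quality control.
* **Two-state photocycle kinetics**: dark recovery
  *A*₄₅₀ = *A*₀ + *A*₁·exp(−k₋₁t), photoactivation under constant
  illumination with observed rate k_obs = k₁ + k₋₁, the photostationary
  dark fraction k₋₁/(k₁+k₋₁), and Arrhenius activation energies from
  ln k vs 1/T.
* **Relative fluorescence quantum yield** by the slope-ratio method,
  Φ_F = Φ_r · (m_F/m_r) · (n_F²/n_r²), against coumarin 153
  (Φ_r = 0.54 in ethanol).
* **Circular dichroism**: conversion to mean residue ellipticity
  [θ]_MRW = θ(mdeg)/(10·c·l·N_res) and light/dark signaling amplitudes.
* **Methionine-frequency profiling** of LOV multiple sequence alignments:
  conserved-residue filtering (≥8 of 10 signature residues, G447 … Q513
  in AsLOV2 numbering) and per-position Met frequencies mapped to
  reference numbering.

Every input the pipeline consumes can be generated by the built-in
synthetic-data module with known ground truth, so each stage is validated
by parameter recovery. Published characterization values for AsLOV2 and
NcVVD variants ship as reference tables (`aslov2_variants()`,
`ncvvd_variants()`).

## Worked example

Simulate a wild-type-like titration at the published midpoint (−278 mV),
then recover it from the spectra alone:

```r
library(lovredox)

refs <- make_reference_spectra("flavin_LOV")
params <- titration_sim_params(analyte_E0_mv = -278, noise_sd = 0.002,
                               seed = 42)
sim <- simulate_titration(params, refs)

fractions <- fractions_over_time(sim$series, refs)
fit_midpoint(fractions$analyte, fractions$indicator)
#> <lov_redox_fit> E0 = -278.0 mV vs NHE (offset -26.0 mV from indicator -252 mV)
#>   slope 0.999 (SE 0.002), 18 points, QC pass
```

The recovered midpoint sits on the true value, the slope is unity
(confirming redox equilibration), and 18 timepoints fell inside the
fraction window where both species are partially reduced.

Dark-recovery kinetics at the published wild-type rate with 1% amplitude
noise:

```r
trace <- simulate_exponential_trace("recovery", rates = 0.013,
                                    times = seq(0, 300, 2),
                                    noise_sd = 0.004, seed = 42)
fit_recovery(trace)
#> <lov_kinetic_fit> recovery: observed rate 0.01295 s-1, A0 0.4499, A1 -0.3984
```

Summary statistics over the published variant table:

```r
rep <- build_report(aslov2_variants(), wild_type = "Wild type")
rep$summary$mean_delta_E0_display
#> [1] 17
```

i.e. methionine introduction raises the flavin reduction midpoint
potential by 17 mV on average across the eleven variants.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "lovredox",
                               load_package = "installed")'
```

The suite covers file-format round-trips, the Nernst inverse pair,
unmixing against a brute-force grid-search oracle, noiseless exactness
and noisy-recovery properties of every estimator, the
equilibration-lag pathology that trips the slope QC, and alignment
filtering/profiling statistics.

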
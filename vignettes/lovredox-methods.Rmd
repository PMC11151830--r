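---
title: "Models and estimators in lovredox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in lovredox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lovredox)
```

This vignette is the package's account of the science behind each
pipeline stage: the models fitted, the assumptions they rest on, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generators do and do not emulate, and where the design
was genuinely open.

## Dye-coupled redox titrations and the Nernst correlation

A reduction midpoint potential $E_0$ is defined by the Nernst relation
for a $z$-electron couple,

$$E = E_0 - \frac{RT}{zF}\,\ln\frac{f_\mathrm{red}}{f_\mathrm{ox}},$$

with $R = 8.314462618$ J mol$^{-1}$ K$^{-1}$ and
$F = 96485.332$ C mol$^{-1}$. Potentials are carried in mV vs NHE
throughout the package; volts appear only inside the Nernst arithmetic.
At the default measurement temperature of 295.15 K (22 °C) and $z = 2$,
the natural-log slope $RT/zF$ is 12.717 mV
(`nernst_slope_mv(2, 295.15)`).

In the chemical-reduction experiment, a reductant (DTT) slowly drives
the solution potential down over several hours while a mediator (methyl
viologen) keeps analyte, indicator dye, and solvent in redox
equilibrium. The flavin analyte is a two-electron quinone/hydroquinone
couple; the indicator, phenosafranine, is a two-electron dye with
$E_{r0} = -252$ mV whose reduced (leuco) form is colorless. Because $z$
is the same for both couples, equating their Nernst relations gives

$$E_0 - E_{r0} = \frac{RT}{zF}\left(\ln\frac{f_\mathrm{red}}{f_\mathrm{ox}}
  - \ln\frac{f_{r,\mathrm{red}}}{f_{r,\mathrm{ox}}}\right),$$

so plotting the indicator log term against the analyte log term must
give a line of unit slope whose axis offset is $E_0 - E_{r0}$. The slope
is a built-in control: deviations from unity indicate that reduction
outpaced equilibration. `fit_midpoint()` flags slopes outside the
configured bounds (default $[0.8, 1.2]$) as failing QC.

**Assumptions.** (i) Redox equilibrium at every sampled timepoint;
(ii) strictly two-state chemistry — no semiquinone accumulates during
chemical reduction, so two basis spectra per species suffice;
(iii) constant total concentrations (closed cuvette, no
photobleaching); (iv) the probe light does not photoactivate the
sample.

### Fraction estimation by spectral unmixing

`unmix_fractions()` decomposes one spectrum into non-negative
least-squares (NNLS) coefficients over the four reference spectra
(analyte ox/red, indicator ox/red) and renormalizes the requested
species' pair to sum to one. NNLS is the right constraint set because
concentrations cannot be negative; the solver is `pracma::lsqnonneg`.
Using the full spectrum subsumes the classical single-wavelength
procedure (indicator read at its 520 nm band, the 450 nm flavin signal
corrected for the indicator's contribution), which remains available as
`fractions_over_time(mode = "two_wavelength")` for comparability.

For a whole titration series, `fractions_over_time()` refines the naive
per-spectrum renormalization in one important way. The reduced
phenosafranine is essentially transparent in the visible, so its NNLS
coefficient is determined by noise, not signal; dividing by the pair sum
would inject that noise into every indicator fraction. Instead the
estimator exploits two facts about the experiment: total concentrations
are constant, and the series starts with both species fully oxidized.
Each species' total spectral amplitude is therefore calibrated from the
oxidized-form coefficient averaged over the first timepoints (default
3), and fractions follow as $f_\mathrm{ox}(t) = c_\mathrm{ox}(t)/c_\mathrm{tot}$.
The reduced-form head coefficient is added to the calibration only when
it exceeds three times its own noise level, estimated from the unmixing
residual — this keeps the estimator exact in the noiseless limit (where
the head coefficient is genuine signal, however small) while excluding
it when it is noise. This mirrors standard bench practice of
normalizing the indicator band decay by its initial amplitude.

### Regression, windowing, and reporting conventions

* **Fraction window** (default $(0.05, 0.95)$): the log terms are
  singular at fractions 0 and 1, so timepoints where either species
  lies outside the window are dropped. The window is an analysis
  parameter of this package; at least 5 usable timepoints are required
  or the fit aborts with "insufficient overlap of redox transitions".
* **Regression direction**: ordinary least squares of the indicator
  term on the analyte term. Errors-in-variables handling is not
  specified by the underlying method; as a diagnostic the inverted-axes
  slope is also computed and a disagreement beyond 20% is logged
  (enable with `options(lovredox.verbose = TRUE)`).
* **Units and rounding**: midpoints are carried at full precision;
  rounding to integer mV happens only in the report layer
  (`build_report()`), matching how such tables are conventionally
  printed (rates to 3 decimals, activation energies to 1 decimal).

## Two-state photocycle kinetics

The photocycle is modeled as two states, dark-adapted D and
light-adapted (thioadduct) L, with light-driven activation rate $k_1$
(proportional to photon flux; defined here at the reference condition of
3 mW cm$^{-2}$ blue light) and thermal recovery $k_{-1}$. Under constant
illumination the 450 nm absorbance decays mono-exponentially with
$k_\mathrm{obs} = k_1 + k_{-1}$ toward the photostationary plateau, at
which the dark fraction is $k_{-1}/(k_1 + k_{-1})$
(`pss_dark_fraction()`). In darkness the signal recovers with $k_{-1}$
alone. The same single-exponential applies to CD-monitored recovery at
208 nm.

`fit_recovery()` and `fit_photoactivation()` use Levenberg–Marquardt
nonlinear least squares (`minpack.lm::nlsLM`, up to 200 iterations) on
$A(t) = A_0 + A_1 e^{-kt}$. Initial guesses are endpoint heuristics
chosen for robustness on monotone single exponentials: $A_0$ from the
last-decile mean, $A_1$ from the first point minus $A_0$, and the rate
from the time at which the amplitude has fallen to $1/e$. Degenerate
inputs fail loudly: constant traces ("no decay detected"), non-positive
fitted rates, illuminated traces passed to the recovery fitter, and
photoactivation fits where the observed rate does not exceed the
supplied recovery rate. A trace spanning less than one fitted half-life
triggers a warning rather than an error. Photoactivation and recovery
are fitted separately — recovery first, then subtracted — rather than
jointly, matching how the experiment is actually run.

Arrhenius analysis (`fit_arrhenius()`) is ordinary least squares of
$\ln k$ on $1/T$, $E_A = -\mathrm{slope} \cdot R$, reported in
kJ mol$^{-1}$. Two distinct temperatures determine the line exactly and
are accepted (standard errors are then NA); three or more are needed for
uncertainties. This is deliberately more permissive than a strict
three-point minimum because the two-point slope is well-defined and
useful as a cross-check.

One caveat the package surfaces rather than hides: rounded published
rate triplets need not be self-consistent. An observed rate of 0.062
with $k_{-1} = 0.013$ yields $k_1 = 0.049$, while unrounded inputs can
give 0.048. The fitters report full precision; reconciliation is left
to the analyst.

## Fluorescence quantum yield and CD conversion

The relative quantum yield uses the slope-ratio method: dilution series
of sample and reference are kept optically thin (absorbance at the
excitation wavelength at most 0.1 by design; the container rejects
values above 0.15, and the simulator warns above 0.1 where inner-filter
effects begin to bias the linear model), integrated emission (450–700 nm,
trapezoidal) is regressed on absorbance, and

$$\Phi_F = \Phi_r \cdot \frac{m_F}{m_r} \cdot \frac{n_F^2}{n_r^2}.$$

The dilution fit uses a free intercept by default because instrument
offsets exist; a zero-intercept variant is available by flag. Refractive
indices default to 1.334 (aqueous buffer) and 1.361 (ethanol), the
standard values for the solvents involved; the reference yield defaults
to coumarin 153's 0.54 in ethanol.

CD signals are converted to mean residue ellipticity as
$[\theta]_\mathrm{MRW} = \theta_\mathrm{mdeg} / (10\, c_M\, l_\mathrm{cm}\, N_\mathrm{res})$,
the standard per-residue molar normalization, with $N_\mathrm{res} = 143$
as default (the AsLOV2 construct spanning residues 404–546). The
light response is reported as the sign-aware fractional change
$(\theta_\mathrm{dark} - \theta_\mathrm{light})/\theta_\mathrm{dark}$ and
is deliberately left as raw arithmetic: published prose sometimes quotes
larger "approximate" amplitudes than the tabulated ellipticities imply,
and the package does not attempt to reconcile the two.

## Methionine profiling of LOV alignments

The sequence module consumes a pre-computed aligned FASTA (homology
search and clustering are upstream and out of scope). Sequences are
filtered by the ten signature residues of LOV domains (G447, N449,
C450, R451, F452, L453, Q454, N482, N492, Q513 in AsLOV2 numbering),
retaining sequences matching at least `min_matches` of them. The
default threshold is 8 of the 10 listed positions: the literature
phrase "eight of nine" conflicts with its own ten-residue list, and the
operational list is taken as authoritative. Gaps count as mismatches in
the filter (the stricter, reproducible choice) but are excluded from
frequency denominators, so a column's Met frequency is over aligned
residues only; all-gap columns report 0 and are flagged. Filtering is
idempotent by construction.

## The synthetic-data generators

The generators are first-class, tested code: they define the conditions
under which every estimator is validated.

* **Reference spectra** are Gaussian mixtures: the oxidized flavin as a
  vibronically structured triple peak with maximum near 450 nm plus a
  near-UV band; the hydroquinone as a near-UV band with negligible
  absorbance above 430 nm; oxidized phenosafranine peaking at 520 nm;
  its leuco form transparent in the visible. `riboflavin` uses the same
  band positions with washed-out vibronic structure, as free flavin
  shows.
* **Potential trajectory**: a single exponential relaxation
  $E(t) = E_\mathrm{end} + (E_\mathrm{start}-E_\mathrm{end})e^{-t/\tau}$
  — the simplest monotone form with one time constant. Defaults: −100
  to −400 mV, $\tau = 7200$ s, 8 h duration, 200 spectra, emulating a
  protracted reduction that fully spans both transitions within several
  hours. The optional equilibration-lag mode relaxes the analyte toward
  its Nernst equilibrium with a first-order rate $k_\mathrm{eq}$
  instead of instantly, reproducing the pathology of a reduction that
  outruns mediation; with $k_\mathrm{eq}$ on the order of $1/\tau$ or
  slower this drives the correlation slope out of the QC band.
* **Amplitudes and noise**: analyte and indicator contribute peak
  absorbances of 0.45 and 0.25 AU (matching tens of µM protein at the
  flavin extinction coefficient and a few µM dye), with i.i.d. Gaussian
  noise of 0.002 AU per wavelength — a realistic diode-array noise
  floor. Rate series carry mean-one multiplicative lognormal noise
  instead, as rate errors are relative.
* **Photoactivation plateau**: the simulator sets the plateau from the
  two-state steady state $k_{-1}/(k_1+k_{-1})$, which makes the
  amplitude terms of the observed exponential self-consistent with the
  kinetic model rather than free parameters.
* **Alignment fixtures** draw Met at each column with a specified
  probability and otherwise a uniform non-Met residue; conserved
  columns carry their signature residue except in a configurable
  fraction of degraded sequences, which receive three violations each —
  the minimum that the default 8-of-10 filter actually removes.

**What the generators do not emulate**: instrument drift and baseline
wander, wavelength miscalibration, semiquinone intermediates,
photobleaching, DTT consumption chemistry (the potential ramp is
phenomenological), scattering, inner-filter effects, and the
phylogenetic correlation structure of real alignments (fixture columns
are independent). Passing recovery tests therefore demonstrate
estimator correctness under the stated statistical model, not
robustness to every artifact of real instruments.

## Problem sizes and determinism

Every simulator is deterministic under a fixed seed, and changing only
the seed changes noise realizations, not the noiseless structure. The
test suite runs titrations at 40–200 timepoints on 1–2 nm grids,
kinetic fits on a few hundred points, and 100-replicate noise studies
for rates, activation energies, and quantum yields — sizes chosen so
the full suite completes in well under a minute while leaving the
statistical assertions well-powered. The acceptance script
(`scripts/acceptance.R`) uses the full default conditions (200 spectra,
0.002 AU noise).

## Known limitations

* Strictly two-state redox chemistry: no semiquinone unmixing; systems
  that populate radical states need a three-component model.
* The indicator's midpoint is taken as known and pH-independent; no
  electrode-based modes.
* OLS (not errors-in-variables) for the Nernst correlation; at unit
  slope and the default noise this bias is negligible, and the
  inverted-axes diagnostic guards against larger disagreement.
* $k_1$ is tied to the calibrated illumination geometry; the intensity
  rescaling in `pss_dark_fraction()` is a linear extrapolation, not a
  measurement.
* The amplitude calibration in `fractions_over_time()` assumes the
  titration starts fully oxidized; series that begin mid-transition
  should use per-spectrum `unmix_fractions()` directly.
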
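---
title: "Ensemble ECD simulation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble ECD simulation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdtools)
```

## The problem

Electronic circular dichroism (ECD) is the difference in molar absorption of
left- and right-circularly polarized light, $\Delta\varepsilon =
\varepsilon_L - \varepsilon_R$ (M$^{-1}$cm$^{-1}$). Because it is exquisitely
sensitive to chirality, it is the workhorse observable for inferring the
solution structure of DNA-derived species — including metal-mediated duplexes
in which Ag$^+$ ions bridge guanine bases in place of hydrogen bonds.
Excited-state calculations (TDDFT) produce *stick spectra*: for each
electronic state $n$, an excitation energy $E_n$ (eV) and a length-gauge
rotatory strength $R_n$ (conventionally in units of $10^{-40}$ cgs).
Comparing with experiment requires (i) broadening the sticks into a
continuous curve, (ii) averaging over a thermal ensemble of
molecular-dynamics snapshots, and (iii) a disciplined way of comparing peak
positions and spotting spurious features. `ecdtools` implements that
pipeline, plus the two pieces of supporting machinery such studies need:
the Coulomb-attenuation parameter scan that morphs a range-separated hybrid
functional into a global hybrid, and the geometric preparation of
backbone-truncated QM models of nucleic acids.

## From sticks to spectra

The broadened spectrum is

$$\Delta\varepsilon(E) = 4a \sum_n R_n\, E_n\, \sigma_n(E), \qquad
\sigma_n(E) = \frac{1}{\sqrt{2\pi}\,\sigma}
e^{-(E-E_n)^2 / 2\sigma^2},$$

a sum of unit-area Gaussians in energy, each weighted by the state's
rotatory strength and excitation energy. The prefactor is computed — never
hard-coded — from CODATA constants as

$$a = \frac{8\pi^3 N_A}{3\ln(10)\,10^3\, h c}$$

with $h$ in erg·s and $c$ in cm·s$^{-1}$, so that $1/(4a) =
2.2965\times10^{-39}$: the familiar conversion constant of chiroptical
post-processing, equivalent to $\Delta\varepsilon(E) = E_n R_n \sigma_n(E) /
(2.296\times10^{-39})$ for $R_n$ in cgs. The energy-axis unit cancels in the
product $E_n\,\sigma_n(E)$, so evaluating in eV is exact, not a further
approximation. `cdPrefactor()` records the derivation string and constant
values in its attributes so the unit reconciliation is a single audited
site; a test cross-checks the single-state convolution against the
$2.296\times10^{-39}$ relation to 2%.

Two energy-weighting conventions exist in post-processing codes: weight by
the state's own excitation energy $E_n$, or by the incident photon energy
$E$. Both are implemented (`BroadeningConfig(energyWeighting=)`); the
default is `per_state_energy`, the convention consistent with the
$\Delta\varepsilon \propto E\,R$ relation of the standard derivations. All
arithmetic is performed in energy space because the half-width $\sigma$ is
an energy; the output grid is reported in nm using
$\lambda = 1239.841984\,\mathrm{eV\,nm}/E$.

Parameters that matter:

* `sigma` — the exponential half-width of the Gaussian, in eV. 0.3 eV is
  the conventional choice for silver-mediated guanine tetramers; 0.2 eV for
  plain B-DNA and guanine tetramers. It is the single most influential
  cosmetic parameter: larger values merge neighbouring bands.
* grid — default 170–400 nm at 0.5 nm. The short-wavelength edge matters
  only insofar as the underlying state list is converged there; the
  convolution itself is exact for whatever states it is given.
* States with tiny $|R_n|$ are never pruned silently; filtering is a caller
  decision.

Numerical checks enforced by the test suite: unit normalization of the
lineshape to $10^{-6}$ (trapezoid quadrature), exact sign antisymmetry,
superposition over unions of states, decay below $10^{-6}\times$ the
maximum at grid points further than $8\sigma$ from every state, and
equality with an independently written brute-force double loop to
$10^{-10}$ relative on random sticks.

## Ensemble averaging and the confidence band

Solution-phase spectra are thermal averages. Snapshots sampled from an
equilibrated trajectory are each convolved, then averaged pointwise; ten
snapshots is the customary count for a solvated guanine tetramer.
`averageSpectra()` resamples members onto the intersection of their spans
at the finest member step (never extrapolating) and computes, by default,
the pointwise Student-t interval of the mean,

$$\bar{y}(\lambda) \pm t_{(1-cl)/2,\,n-1}\; s(\lambda)/\sqrt{n},$$

appropriate for small $n$. How published 95% bands of this kind are
computed is often unstated; rather than guess, a seeded bootstrap
percentile band (2000 resamples) is provided alongside the t band
(`method = "bootstrap"`) so both can be reported. A Monte-Carlo experiment
in the test suite (2000 replicates of $n = 10$ Gaussian-noise ensembles
around a known two-band curve) confirms the t band's pointwise coverage is
95% ± 1.5%. A single-member "ensemble" degenerates to a zero-width band
with an explicit warning. The estimator assumes members are independent —
appropriate for sparsely sampled snapshots, not for densely correlated
trajectory frames (a deliberate non-goal).

Mirror-image spurious features in individual members cancel in the mean;
this cancellation — the reason ensemble averaging suppresses
single-snapshot artifacts in the long-wavelength region — is tested with
constructed antisymmetric member pairs.

## Peak diagnostics

`findPeaks()` reports local extrema by topographic prominence: maxima with
positive amplitude as positive peaks, minima with negative amplitude as
negative peaks. Prominence (default floor 1 M$^{-1}$cm$^{-1}$) suppresses
grid-scale ripples without thresholding genuine shoulders. Positions are
grid-resolution quantities; an optional parabolic refinement exists but is
off by default because experimentally quoted ECD peak positions carry
~10 nm granularity. `matchPeaks()` pairs calculated against experimental
peaks greedily by nearest position without replacement (ties broken toward
the shorter-wavelength pair for deterministic reports); the verdict flag is
true when every matched $|$shift$|$ is within the tolerance, default 20 nm
— the conventional agreement window for ECD peak positions of these
systems. `positiveFeature()` is the spurious-shoulder diagnostic: the
maximum positive $\Delta\varepsilon$ in a window (default 220–240 nm,
where over-exact-exchange functionals produce a positive shoulder for
silver-mediated guanine duplexes that experiment does not show), exactly 0
for all-negative spectra.

A limitation worth knowing: under independent per-point noise, the
detected position of a *broad, shallow* band wanders. The Monte-Carlo
stability test documents this: at noise of 5% of the global amplitude, the
deep ~210 nm band's detected position is stable to the grid (median
displacement ≤ 2 nm) while the flat-topped ~275 nm band's median
displacement is ~3 nm with excursions up to ~11 nm. Tightening that would
require band fitting, which is out of scope by design.

## The attenuation-parameter path

In a Coulomb-attenuated hybrid functional the Hartree–Fock exchange
fraction depends on interelectronic distance as
$\alpha + \beta\,\mathrm{erf}(\mu r_{12})$: $\alpha$ at $r_{12}=0$,
$\alpha+\beta$ at infinity, with $\mu$ (bohr$^{-1}$) setting the midpoint.
CAM-B3LYP has $(\alpha,\beta,\mu) = (0.19, 0.46, 0.33)$; with
$(0.20, 0, \cdot)$ the form reduces to B3LYP. `parameterPath()` linearly
interpolates $(\alpha,\beta)$ between two parameter sets at equally spaced
fractions, holding $\mu$ fixed at the start value (the convention when
morphing CAM-B3LYP into B3LYP), reproducing the endpoints exactly; the
5-point default yields $(0.1925, 0.3450)$, $(0.1950, 0.23)$,
$(0.1975, 0.1150)$ at the interior points. `emitOverrides()` renders each
point as a deterministic stanza with integer-scaled fields
(value × 10$^4$, the ten-thousandths convention of QC parameter
overrides); the 10$^{-4}$ encoding resolution is validated at emit time so
decode∘emit is exact. Mapping the fields onto a particular code's override
keywords is left to the user and documented as such.

## Structure preparation

For tetramer-scale QM models the sugar–phosphate backbone is removed and
the severed glycosidic valences are capped with hydrogens.
`stripBackbone()` removes the standard backbone/sugar atom-name set (P,
OP1/OP2 and variants, O5′, C5′, C4′, O4′, C3′, O3′, C2′, O2′, C1′, and
their hydrogens; asterisked dialect names are normalized to primes) from
residues recognized as nucleotides, passing every other species (Ag$^+$,
waters) through untouched, and records one cut bond per residue at
C1′–N9 (purines) or C1′–N1 (pyrimidines). `capWithHydrogens()` places one
H per cut along the unit vector from the glycosidic nitrogen toward the
removed C1′ at 1.01 Å — the standard amine N–H length, configurable. This
fixed-length placement is a declared geometric convention for the
*pre-relaxation* guess; quantum-mechanical relaxation of the caps is
outside scope. Stripping is idempotent, capping never moves pre-existing
atoms, and the element inventory after strip+cap contains no phosphorus or
sugar atoms — all enforced by tests.

## The synthetic-data generator

No quantum-chemistry outputs ship with the package; the generator stands
in for snapshot TDDFT results so the whole pipeline is exercisable
end-to-end. A recipe describes electronic bands — (center energy, mean
rotatory strength, states per band) — and per-snapshot Gaussian jitter of
state energies and rotatory strengths around those means. Gaussian jitter
is the simplest model of thermally fluctuating snapshot spectra; it is a
modelling choice of this package, not a claim about any particular
system's statistics. The defaults emulate the phenotype of a
silver-mediated guanine duplex ensemble: ten snapshots, two negative bands
at 5.90 eV (~210 nm, mean $R = -25$) and 4.51 eV (~275 nm, mean
$R = -15$), three states per band, energy jitter 0.05 eV, fractional $R$
jitter 0.10 — amplitudes chosen so the broadened mean lands in the tens of
M$^{-1}$cm$^{-1}$, the scale of measured guanine-duplex ECD. Seeding is
hierarchical: one root seed draws per-snapshot substream seeds, so
ensembles are bit-identical across calls and zero jitter collapses all
snapshots onto the band centers. A law-of-large-numbers test (2000
snapshots) confirms per-band mean energies converge to the recipe centers
within 3 standard errors.

What passing synthetic tests do **not** show: that any functional's real
spectra look like the recipe. The generator produces band-limited Gaussian
ensembles with independent snapshots; real snapshot spectra have
state-crossing, intensity borrowing and correlated fluctuations the recipe
does not model. The synthetic experiments validate the *machinery*
(convolution, averaging, detection, comparison), not electronic-structure
conclusions.

## Problem sizes and determinism

The shipped experiments use deliberately desk-scale sizes: 0.5 nm grids
over 170–400 nm (461 points), ten-member ensembles, 2000-replicate
coverage and bootstrap runs, 100-seed stability scans, and sub-second
structure fixtures. Every stochastic stage takes an explicit seed;
`runPipeline()` writes a manifest with the config echo, package and R
versions, the seed, and an MD5 checksum of every output file, and two runs
from the same config produce byte-identical numeric outputs. Degenerate
inputs are handled loudly: empty stick spectra convolve to exact zero,
single-member ensembles warn, extrapolation in resampling, disjoint
feature windows and malformed input rows are typed errors naming the
offending file, line or residue.
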
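---
title: "Restricted LET and RBE outside small megavoltage photon fields: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restricted LET and RBE outside small megavoltage photon fields: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penumbralet)
```

## The problem

In photon radiotherapy the tissue just outside a treatment field receives a
low but non-negligible dose, and the *quality* of that radiation — how densely
it ionises — differs from the in-field beam. The photon fluence beyond the
field edge is dominated by scattered, softened photons, which set in motion
slower electrons with a higher linear energy transfer (LET). Since biological
effect per unit dose rises with LET, the out-of-field region can be
biologically more effective per gray than the field centre. This package
quantifies that effect for small 6 MV fields through three quantities per
geometry point (field size, water depth, off-axis distance):

* the **track-average restricted LET** $L_{\Delta,T}$ of the electron fluence,
* the **dose-average restricted LET** $L_{\Delta,D}$, and
* a predicted **maximum low-dose RBE** ($\mathrm{RBE}_M$) for the dicentric
  chromosome-aberration endpoint in human lymphocytes, relative to
  $^{60}$Co $\gamma$ rays.

## LET moments of an electron spectrum

For a fluence spectrum $\Phi(E)$ (particle fluence differential in kinetic
energy, scored down to the delta-ray cutoff $\Delta$) the two averages are

$$
L_{\Delta,D}
 = \frac{\int_\Delta^{E_{max}} L_\Delta^2(E)\,\Phi(E)\,dE
          + S^2(\Delta)\,\Phi(\Delta)\,\Delta}
        {\int_\Delta^{E_{max}} L_\Delta(E)\,\Phi(E)\,dE
          + S(\Delta)\,\Phi(\Delta)\,\Delta},
\qquad
L_{\Delta,T}
 = \frac{\int_\Delta^{E_{max}} L_\Delta(E)\,\Phi(E)\,dE
          + S(\Delta)\,\Phi(\Delta)\,\Delta}
        {\int_\Delta^{E_{max}} \Phi(E)\,dE + \Phi(\Delta)\,\Delta},
$$

where $S$ is the unrestricted and $L_\Delta$ the $\Delta$-restricted collision
stopping power of liquid water. The $S(\Delta)\Phi(\Delta)\Delta$ terms are a
track-end correction: electrons whose energy falls below $\Delta$ deposit the
remainder locally. By the Cauchy–Schwarz inequality
$L_{\Delta,D} \ge L_{\Delta,T}$ for every spectrum, with equality only when
the spectrum is effectively monoenergetic in $L_\Delta$; this ordering is
enforced as a test invariant. Both ratios are invariant under rescaling of
$\Phi$, so the absolute normalisation of a spectrum never matters.

Two conventions deserve comment:

* **Weighting.** The formulas are implemented with particle fluence, the
  dimensionally standard choice for these moments. Because usage in the field
  is occasionally ambiguous ("energy fluence" sometimes denotes
  $E\,\Phi(E)$), `weighting = "energy"` re-weights by $E\,\Phi(E)$ for
  sensitivity analysis. On typical slowing-down spectra the energy-fluence
  track average is lower, since it emphasises fast, low-LET electrons.
* **Quadrature.** Integrals are midpoint sums over bins, with $L_\Delta$
  interpolated log-log at geometric bin midpoints. Halving the bin widths of
  a smooth spectrum moves either moment by well under 0.2% (tested).

The default cutoff is $\Delta = 1$ keV throughout, matching common practice
for megavoltage beam-quality work; it is configurable everywhere.

## Stopping powers

`collision_stopping_power()` and `restricted_let()` implement the closed
ICRU-37-style forms built from the Møller cross-section for
electron–electron collisions: the restricted mass collision stopping power is

$$
L_\Delta/\rho = \frac{k\,(Z/A)}{\beta^2}
  \left[\ln\!\frac{\tau^2(\tau+2)}{2\,(I/m_ec^2)^2} + G^-(\tau,\eta) - \delta\right],
$$

with $\tau = E/m_ec^2$, $\eta = \Delta/E \le 1/2$, $k = 2\pi r_e^2 m_ec^2 N_A$,
and $G^-(\tau, 1/2)$ recovering the familiar unrestricted stopping number.
Radiative losses are excluded by definition — LET is collisional. Checks worth
knowing about:

* The identity $L_\Delta \equiv S$ for $E \le 2\Delta$ holds *exactly* (the
  code clamps $\eta$ at $1/2$), and the difference $S - L_\Delta$ for
  $E > 2\Delta$ agrees with direct numerical integration of the
  energy-weighted Møller cross-section at machine precision; the test suite
  re-derives that integral independently with `stats::integrate()`.
* The density-effect correction uses the Sternheimer parameterisation. The
  bridge coefficient $a$ is derived from the other coefficients by requiring
  exact continuity at $x_0$ rather than stored as a fitted constant: the
  published fitted value (0.09116 for water) makes $\delta$, and hence
  $S(E)$, jump by $\sim 10^{-4}$ relative at $x_0$, while the derived value
  (0.09109, within 0.1% of the fit) keeps the stopping power continuous to
  numerical precision — a property the tests assert at both breakpoints.
* The mean excitation energy defaults to $I = 75$ eV, the ICRU-37-era
  convention consistent with the EGSnrc-generation toolchains this analysis
  emulates; ICRU 90 recommends 78 eV. Density 1.000 g/cm³. Both live in a
  plain CSV (`extdata/materials.csv`), not in code.
* Below 1 keV kinetic energy the Bethe formula is unreliable; evaluation
  errors rather than extrapolates (`floor_keV` argument).

Tables built by `build_stopping_table()` default to 200 log-spaced energies
from 1 keV to 6.5 MeV; consumers interpolate log-log linearly, which
reproduces direct evaluation within 0.5% even midway between grid points.

## The synthetic spectrum generator

The published LET tables derive from full Monte Carlo radiation transport of
a clinical linac, which is not reproducible on a desktop from the reported
settings alone. The package therefore ships a deterministic emulator
(`generate_case()`) whose role is to produce electron fluences with the
*structure* of the real ones:

1. **Photon spectrum** (`generate_photon_spectrum()`): a filtered
   thin-target bremsstrahlung form
   $k^{-p}\,(1-k/E_{max})\,e^{-f/k}$ (defaults $p = 1.35$, $f = 0.07$ MeV,
   $E_{max} = 6$ MeV), hardened with depth via a water attenuation contrast
   ($0.55\times$ nominal), mixed beyond the field edge with a soft scattered
   component (gamma shape, mean $\approx 0.2$ MeV) whose weight rises as
   $0.9\,(1 - e^{-d/1\,\mathrm{cm}})$ with distance $d$ past the edge.
2. **Electron source** (`compton_electron_source()`): Klein–Nishina
   recoil-electron quadrature over the photon spectrum. Compton scattering
   dominates set-in-motion for 6 MV photons in water; pair production and
   photoelectric absorption are neglected (documented approximation). The
   quadrature reproduces the closed-form Klein–Nishina total cross-section
   to 0.2% in tests.
3. **Slowing-down fluence** (`slowing_down_spectrum()`): the equilibrium
   form $\Phi(E) = Q(>E)/S(E)$ with the Møller knock-on source (delta rays
   above $\Delta$, all generations) iterated to a 0.1% fluence change per
   sweep. The secondary-only spectrum is the converged total minus the
   primaries-only fluence. Energy bookkeeping closes: deposition implied by
   $\int \Phi S\,dE$ plus the track-end term equals the source energy input
   within 2% (tested), and for a monoenergetic source without secondaries
   the fluence is the textbook CSDA form $N/S(E)$ pointwise.

The generator is pure quadrature — identical inputs give bitwise-identical
outputs. The beam-model `seed` only drives an optional log-normal
noise-injection mode used in robustness tests, and that mode saves and
restores the global RNG state.

**Calibration status and limits.** The scatter and softness defaults were
chosen once, by a parameter sweep, so that the generated fluences land in the
LET bands the published Monte Carlo tables span; they are emulation
parameters, not measurements. With the defaults, the 180-geometry grid gives
TEF dose-average LET 2.05–2.63 keV/μm (2 cm beyond the edge: 2.46–2.63,
inside the published 2.45–2.98) and SE 6.10–7.06 keV/μm, with the published
orderings (SE > TEF everywhere; centre ≈ edge < edge+1 < edge+2 beyond
build-up depth; +11–21% centre→edge+2). What the emulator does *not*
reproduce: the absolute in-field TEF dose-average level (it sits ~0.3 keV/μm
below the published 2.4–2.5, because the CSDA slowing-down form carries less
very-low-energy fluence than condensed-history transport), field-size
dependence at fixed position (the scatter model depends only on distance
past the edge), and the near-surface contaminant-electron effects the
published surface-depth rows show. Passing band and ordering tests therefore
validates the analysis chain, not the transport fidelity of the emulator.

## RBE calibration

`fit_rbe_curve()` fits $\mathrm{RBE}_M$ against photon energy with a degree-2
polynomial, by default in $\log_{10} E$ (calibration energies span
two-plus orders of magnitude; a linear coordinate is available) and
inverse-variance weighted by the stated uncertainties. The coefficient
covariance of the weighted fit is $(X^\top W X)^{-1}$ — propagation of the
declared measurement uncertainties — and predictions propagate it to first
order. Quadratics diverge outside their support, so `predict_rbem()` clamps
out-of-range energies to the boundary value and flags them instead of
extrapolating.

Each geometry is mapped to the calibration axis through the fluence-weighted
mean photon energy (`effective_photon_energy()`). This mapping is a package
convention: how the published per-position RBE values were anchored to photon
energy is not recoverable from the source tables, so the effective-energy
operation is an explicit, replaceable stand-in.

The packaged calibration table is **synthetic** (see
`read_rbe_calibration()`): the dicentric data the analysis builds on are
available to us only graphically, so the fixture emulates their shape — unity
at the $^{60}$Co reference, rising to $\approx 3$ near 5 keV, with the
$\sim$30% standard uncertainties typical of cytogenetic data. Simulation
tests show the weighted fit recovers known coefficients within 3 standard
errors in well over 95% of noisy replicates, and exactly on noiseless
parabolic data.

## The published-table fixture and summary statistics

`load_published_tables()` returns the packaged transcription of the four
published result tables: 180 rows (9 fields × 5 positions × 4 depths) of
track/dose-average LET for both spectrum kinds plus predicted
$\mathrm{RBE}_M$, validated on load (schema, row count, dose > track per
row). The inconsistent 19.85/19.9 cm depth label of the source is normalised
to 19.9 cm. `summarize_out_of_field()` computes the headline statistics: the
range of dose-average LET 2 cm beyond the edge (TEF max 2.980 keV/μm, SE max
7.386), per-field percent increases from centre to edge+2 (up to 21.6% at
d$_{max}$), and per-depth ratios of maximum out-of-field to minimum in-field
$\mathrm{RBE}_M$ (1.97 at 1.35 cm — the "factor of two" out-of-field
enhancement). All quoted LET values carry a combined standard uncertainty of
0.6% ($k = 1$), attached as `rel_u`.

## Numerical choices at a glance

| Choice | Default | Why |
|---|---|---|
| Cutoff $\Delta$ | 1 keV | standard for megavoltage beam-quality analysis |
| Energy grid | 200 log bins, 1 keV–6.5 MeV | covers the 6 MV Compton edge with <0.5% interpolation error |
| Bin midpoints | geometric | natural for log grids |
| Knock-on iteration | 0.1% sweep tolerance, cap 50 | converges in ~5 sweeps on realistic spectra |
| $I$, $\rho$ (water) | 75 eV, 1.000 g/cm³ | toolchain-era convention, configurable |
| Position tolerance | 0.01 cm | matches the resolution of the studied geometry grid |
| `rel_u` | 0.006 | quoted combined standard uncertainty ($k=1$) |

Problem sizes used in the shipped tests and the acceptance script — the full
180-geometry grid, 200-point energy grids, 1,000 randomised spectra for the
ordering property, 200 calibration replicates — were chosen so the whole
suite reruns in well under a minute of CPU while still exercising every
stage at the sizes the analysis actually uses.

## Known limitations

* The emulator's fidelity limits above; it is a structured stand-in, not a
  transport code (no angular distributions, no 3-D geometry, no
  contaminant-electron modelling by default).
* Only the two scalar LET averages are computed — no microdosimetric
  distributions.
* The RBE chain is a single-endpoint calibration; no mechanistic model, no
  dose/dose-rate dependence, and the packaged calibration data are synthetic.
* Liquid water is the only shipped material, though `material_spec()` is
  generic.
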
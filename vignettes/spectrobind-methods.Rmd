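---
title: "Models and methods in SpectroBind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in SpectroBind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpectroBind)
```

SpectroBind implements the standard multi-spectroscopic workflow for
characterizing the binding of a small molecule to a protein — serum
albumin titrated with a flavonoid being the motivating system — as a
set of composable, individually testable stages. This vignette explains
each model, its assumptions, the tunable parameters, the numerical
choices made where the design was genuinely open, and what the
synthetic-data validation does and does not demonstrate.

## Quenching and binding

The Stern–Volmer model, $F_0/F = 1 + K_{SV}[Q]$, is fitted by
unweighted ordinary least squares **with a free intercept**. Forcing
the intercept to 1 would hide miscalibration; instead the fitted
intercept is kept as a diagnostic and should be close to 1 on clean data.
The $[Q] = 0$ point is excluded from the regression: its ratio is 1 by
definition, so including it over-weights an exact point relative to the
measured ones. The reported uncertainty is the standard error of the
slope, and $R$ is the Pearson correlation of $F_0/F$ with $[Q]$.

The quenching rate constant is $k_q = K_{SV}/\tau_0$ with
$\tau_0 = 10^{-8}$ s by default (the conventional unquenched lifetime
of serum albumin's intrinsic fluorophores); $\tau_0$ is a parameter,
not a constant. Mechanism classification deliberately demands **both**
criteria jointly: "static" needs $K_{SV}$ non-increasing with
temperature *and* every $k_q$ above the diffusion-limited collisional
ceiling ($2 \times 10^{10}$ L mol$^{-1}$ s$^{-1}$ by default);
"dynamic" needs the reverse of both. Conflicting evidence returns
"indeterminate" with both facts reported rather than a forced call.
Temperatures are treated as data attached to each series, never as
package constants.

The double-logarithm binding fit,
$\lg[(F_0-F)/F] = \lg K_a + n \lg[Q]$, uses base-10 logarithms as the
notation implies, with $K_a = 10^{\text{intercept}}$ and
$SD(K_a) = K_a \ln(10)\, SE_{\text{intercept}}$ by first-order error
propagation. Points with $F \ge F_0$ (negative quench, possible under
noise) have no defined logarithm; they are **dropped with a warning**
rather than clamped, because clamping would bias the fit silently while
dropping is auditable. An inner-filter correction
($F\,10^{(A_{ex}+A_{em})/2}$) is available but off by default; apply it
only when the absorbances were actually measured.

Site-marker competition operationalizes "significantly decreased" as a
percent-decrease threshold, default 50%, combined with arg-max over
markers; the marker-to-site map (warfarin → Site I, ibuprofen →
Site II) is configuration. Exact ties return "unresolved" with a
warning rather than an arbitrary winner.

## Thermodynamics

The Van't Hoff fit $\ln K_a = -\Delta H^0/(RT) + \Delta S^0/R$ assumes
a temperature-independent enthalpy over the fitted range (the
two-parameter model; no heat-capacity curvature). $\Delta G^0$ is
reported by **both** routes: $\Delta H^0 - T\Delta S^0$, which is the
headline value because it is arithmetically consistent with the fitted
parameters, and $-RT \ln K_a$, which needs no fit and serves as a
per-temperature cross-check. On data generated exactly from a Van't
Hoff law the two agree to machine precision; on real data their gap
measures model adequacy. Units are kJ mol$^{-1}$ for $\Delta H^0$ and
$\Delta G^0$ and J mol$^{-1}$ K$^{-1}$ for $\Delta S^0$.

Force typing follows the usual sign rules — $\Delta H^0 < 0,
\Delta S^0 > 0$: electrostatic (with hydrophobic contribution);
both positive: hydrophobic; both negative: hydrogen bonding / van der
Waals — with exact zeros mapped to "indeterminate" so the function is
total. The kcal→kJ conversion defaults to the international-table
calorie (4.1868 J/cal) because docking programs conventionally report
IT-calorie energies; the thermochemical 4.184 is one argument away.

## Förster energy transfer

The chain is $E = 1 - F/F_0$, $J = \sum F\varepsilon\lambda^4
\Delta\lambda / \sum F \Delta\lambda$ (trapezoid weights after linear
interpolation of the acceptor onto the donor grid restricted to the
common range), $R_0^6 \propto k^2 n^{-4} \Phi J$, and
$r = R_0[(1-E)/E]^{1/6}$. The published literature mixes unit systems
for the $R_0$ coefficient, and printed $(J, R_0)$ pairs are often not
mutually consistent under any single reading. SpectroBind therefore
supports two explicit conventions — `"standard"`
($8.79\times10^{-5}$, $J$ in nm$^4$ M$^{-1}$ cm$^{-1}$, $R_0$ in Å
converted to nm) and `"paper"` ($8.78\times10^{-23}$ applied literally
to $J$ in cm$^3$ L mol$^{-1}$) — and treats the $(E, R_0) \to r$
inversion as the canonical, convention-free step. The defaults
$k^2 = 2/3$ (isotropic dynamic averaging), $n = 1.336$ (aqueous
buffer) and $\Phi = 0.118$ (albumin tryptophan) are conventions, not
measurements; override them when better values exist. Validity flags
($r < 7$ nm; $0.5R_0 < r < 1.5R_0$, strict inequalities at the
boundaries) are reported, never enforced.

The donor spectrum need not be normalized — the denominator of $J$
cancels any scale, and a property test asserts this invariance.
Trapezoid quadrature converges at second order in the grid spacing;
the simulator's analytic reference is computed on a 10× finer grid.

## Conformation metrics

Peak localization throughout the package is **grid-based** (no sub-grid
interpolation), because instruments report peaks on their scan grids;
ties break toward the smaller axis value so the rule is deterministic.
The percent-intensity-change convention is positive-for-decrease,
matching how quench percentages are quoted. Excitation–emission
matrices exclude first- and second-order Rayleigh ridges
($|\lambda_{em}-\lambda_{ex}|$ and $|\lambda_{em}-2\lambda_{ex}|$
within a half-width, default 15 nm — standard EEM practice) before
local-maximum search.

The CD chain uses the two-anchor formula
$\alpha$-helix % $= 100(-\mathrm{MRE}_{208} - 4000)/29000$; no
basis-set deconvolution (CDSSTR/SELCON) is attempted. The default path
length is 0.1 cm (a 1 mm cell) and the albumin residue count 585. Out
of range MRE values are clamped with a warning.

Amide-I decomposition fits a sum of **Gaussian** bands — the simplest
reproducible shape family; Voigt profiles would add parameters the
data cannot constrain — plus a linear baseline co-estimated with the
bands, so band tails at the region edges are not mistaken for
baseline. Band windows (β-sheet 1610–1640, random coil 1640–1648,
α-helix 1648–1660, β-turn 1660–1680, β-antiparallel 1680–1695
cm$^{-1}$) follow common assignment conventions and are configuration,
not constants. Initialization is two-stage: amplitudes are solved
linearly at the configured centers and a common starting width, then
everything is refined by bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`, centers bounded within their windows, widths in
[2, 15] cm$^{-1}$, tight `ftol`/`ptol` so noiseless envelopes are
recovered to numerical precision). Fractions are area ratios and sum
to 100 exactly by construction. Multi-start experiments showed the
residual minimum is reached from generic starts; remaining seed-level
scatter in noisy recoveries is statistical, caused by genuine area
trade-off between heavily overlapping neighbors (notably random coil
vs α-helix), not by the optimizer.

## Antioxidant stage

The scavenging percentage defaults to the standard
$100(A_{control}-A_{sample})/A_{control}$; a `"literal"` mode computes
the occasionally-printed (dimensionally inconsistent)
$100(A_{control}-A_{sample}/A_{sample})$ purely for auditing published
arithmetic. IC$_{50}$ defaults to a two-parameter log-logistic fit with
asymptotes fixed at 0% and 100% — the assay response is bounded by
construction, so freeing the asymptotes only destabilizes small
designs — initialized from the interpolated 50% crossing. A monotone
linear-interpolation method is available; results are flagged
`extrapolated` when the data never cross 50% or the estimate leaves the
measured span.

## The synthetic-data generators

The generators' defaults are the study conditions of the motivating
titration design: protein at $2.5\times10^{-6}$ M, quencher from 0 to
$2.5\times10^{-5}$ M in $2.5\times10^{-6}$ M steps, excitation 280 nm,
a Gaussian emission band at 327 nm (width 25 nm, amplitude 1500 a.u. —
a typical instrument scale), temperatures 288/298/310 K, and a binding
law with $\Delta H^0 = -14.12$ kJ mol$^{-1}$,
$\Delta S^0 = 43.57$ J mol$^{-1}$ K$^{-1}$, $n = 1$. The per-step red
shift defaults to 0.2 nm — a "slight" shift on a nanometre grid.
Amide-I band widths default to $\sigma$ = 9/5/7/7/4 cm$^{-1}$
(FWHM ≈ 10–21 cm$^{-1}$, the range component bands show in protein
infrared work) with the composition of a predominantly helical serum
protein; the DPPH curve defaults to IC$_{50}$ = 9.653 µg mL$^{-1}$
with Hill slope 1.2 on the 1–50 µg mL$^{-1}$ dilution ladder. Noise is
Gaussian, expressed as a fraction of the relevant signal maximum, on a
single explicitly seeded stream per dataset.

Each generator is a right-inverse of its analysis stage at zero noise,
and this is asserted by tests. What the generators do **not** emulate:
inner-filter effects, photobleaching, detector nonlinearity, scatter
other than the idealized Rayleigh ridges, correlated (pink) noise, and
baseline drift beyond a linear term. Passing recovery tests therefore
demonstrates the correctness of the estimators under the stated model,
not robustness to every instrumental artifact of real spectra.

## Validation design and problem sizes

Deterministic identities (Gibbs routes, efficiency/distance inversion,
unit conversions) are tested to $10^{-9}$–$10^{-12}$ relative.
Noiseless round trips through the OLS stages recover generating
parameters to $10^{-9}$ relative; the iterative band fit recovers
fractions to ~$10^{-4}$ points, the practical floor of a bounded
nonlinear optimizer.

Stochastic recovery is assessed on the **Monte-Carlo aggregate**: the
median fitted $K_a$ over 100 seeds at 1% intensity noise (within 10%
of truth), the median IC$_{50}$ over 100 seeds at 1% absorbance noise
(within 5%), and the mean amide-I composition over 50 seeds at 0.1%
noise (within 3 points per class). The aggregate is the right target
because single-seed double-log estimates are intrinsically
high-variance: the intercept extrapolates several decades beyond the
measured $\lg[Q]$ range, so slope noise is amplified exponentially —
a property of the estimator, visible in its closed form, not a defect
of the implementation. Individual-seed dispersion is therefore a
caveat to carry into real-data use: replicate titrations before
trusting a single $K_a$ to better than a few tens of percent at 1%
noise.

These ensemble sizes (100/100/50 seeds, ten-point titrations,
0.5 cm$^{-1}$ infrared grids) keep the full validation suite to a few
seconds while leaving Monte-Carlo error well below the tolerances
being asserted.

## Known limitations

- No combined static+dynamic (sphere-of-action) quenching model, no
  ligand-depletion correction, no global multi-site equilibria.
- CD analysis is the two-anchor 208 nm formula only.
- Amide-I fitting has no Fourier self-deconvolution or
  second-derivative band finding; strongly overlapped compositions
  carry the statistical trade-off noted above.
- The `"paper"` FRET convention reproduces literal published
  arithmetic and is intentionally not unit-coherent.
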
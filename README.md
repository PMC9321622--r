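# SpectroBind

Analysis of multi-spectroscopic ligand–protein binding experiments in R,
built for the workflow used to characterize how small molecules
(flavonoids, drugs) bind serum albumin: fluorescence quenching
titrations, thermodynamic force typing, Förster energy transfer,
site-marker competition, conformational-change metrics and antioxidant
attenuation. Every stage has a matching ground-truth simulator, so the
whole pipeline is testable by parameter recovery without any instrument
data.

## The models

**Stern–Volmer quenching.** A quencher at concentration [Q] reduces the
protein's intrinsic fluorescence from F₀ to F as

    F₀/F = 1 + K_SV [Q] = 1 + k_q τ₀ [Q]

K_SV is the quenching constant (slope of F₀/F vs [Q]) and
k_q = K_SV/τ₀ the bimolecular quenching rate constant, with τ₀ ≈ 10⁻⁸ s
for serum albumin. k_q far above the diffusion limit (2×10¹⁰
L·mol⁻¹·s⁻¹) together with K_SV falling as temperature rises indicates
*static* quenching — a ground-state complex.

**Binding constant and stoichiometry.** For static quenching,

    lg[(F₀ − F)/F] = lg K_a + n lg[Q]

gives the apparent binding constant K_a (10^intercept) and the number of
binding sites n (slope).

**Van't Hoff thermodynamics.** From K_a at several temperatures,
ln K_a = −ΔH⁰/(RT) + ΔS⁰/R yields ΔH⁰ and ΔS⁰;
ΔG⁰ = ΔH⁰ − TΔS⁰ = −RT ln K_a. The signs of (ΔH⁰, ΔS⁰) classify the
dominant force (electrostatic / hydrophobic / hydrogen bonding–van der
Waals, Ross–Subramanian style).

**Förster energy transfer.** E = 1 − F/F₀ = R₀⁶/(R₀⁶ + r⁶), with
R₀⁶ ∝ k² n⁻⁴ Φ J and the overlap integral
J = Σ F(λ) ε(λ) λ⁴ Δλ / Σ F(λ) Δλ, giving the donor–acceptor distance
r = R₀[(1−E)/E]^{1/6}.

**Conformation.** Synchronous-fluorescence quench slopes (Δλ = 15 nm:
tyrosine; 60 nm: tryptophan), 3D-fluorescence peak metrics, CD mean
residue ellipticity MRE = θ_obs/(10 c_p n l) with
α-helix % = 100(−MRE₂₀₈ − 4000)/29000, and Gaussian decomposition of
the FTIR amide-I band (1600–1700 cm⁻¹) into secondary-structure
fractions.

**Antioxidant attenuation.** DPPH scavenging % =
100(A_control − A_sample)/A_control, a log-logistic dose–response fit
for IC₅₀, and the free-vs-protein-complexed IC₅₀ ratio.

## Worked example

A noiseless synthetic titration generated from the binding law
ΔH⁰ = −14.12 kJ·mol⁻¹, ΔS⁰ = 43.57 J·mol⁻¹·K⁻¹ at 288/298/310 K:

```r
library(SpectroBind)

sim  <- simulateTitration(noise = 0)          # 0–25 µM quencher, 3 temperatures
fits <- lapply(sim$series, sternVolmerFit)
fits[[1]]
#> Stern-Volmer fit @ 288 K: Ksv = 6.87e+04 L/mol (SD 7.8e-12), Kq = 6.87e+12 L/mol/s, R = 1.0000

classifyQuenching(fits)$mechanism
#> [1] "static"

ka <- sapply(sim$series, function(s) bindingConstant(doubleLogFit(s)))
vantHoffFit(ka, sapply(sim$series, temperature))
#> Van't Hoff: dH = -14.12 kJ/mol, dS = 43.57 J/mol/K (R = 1.0000)
#>   T = 288 K: dG = -26.67 kJ/mol (dH-TdS) | -26.67 kJ/mol (-RT lnKa)
#>   T = 298 K: dG = -27.10 kJ/mol (dH-TdS) | -27.10 kJ/mol (-RT lnKa)
#>   T = 310 K: dG = -27.63 kJ/mol (dH-TdS) | -27.63 kJ/mol (-RT lnKa)
#>   dominant forces: electrostatic (with hydrophobic contribution)
```

K_SV falls with temperature while every K_q ≈ 5×10¹² L·mol⁻¹·s⁻¹ sits
far above the 2×10¹⁰ collisional ceiling, so the mechanism is static;
the recovered ΔH⁰/ΔS⁰ match the generating law exactly and the negative
ΔG⁰ values show spontaneous binding dominated by electrostatic (plus
hydrophobic) interactions.

The distance chain works from printed numbers alone:

```r
donorAcceptorDistance(0.1574, 2.3749)   # E, R0 (nm)
#> [1] 3.141098
```

`runPipeline(runConfig(...))` runs every configured stage from plain
text inputs (see `simulateBundle()` for the file formats) and
`writeReport()` emits JSON plus Markdown tables.

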
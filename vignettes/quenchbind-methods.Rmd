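---
title: "Models and methods behind quenchbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quenchbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

quenchbind implements the standard multi-spectroscopic workflow for
characterising how a small molecule binds a fluorescent protein such as
serum albumin. This vignette is the package's account of the underlying
science: the models and their assumptions, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate,
the numerical choices, and the known limitations.

## The measurement model

A titration series records the fluorescence intensity of a fixed protein
concentration (the emulated conditions: 2 µM albumin, excitation 279 nm,
emission 341 nm) at a ladder of ligand ("quencher") concentrations,
typically 0–100 µM in 10 µM steps, at one temperature. The point at
[Q] = 0 supplies the unquenched reference F₀; it is taken strictly from
that point and never extrapolated, because every downstream model is a
ratio against it.

Concentrations are stored internally in mol/L; the CSV dialect reads µM by
default (`unit_config`) since bench records are usually in µM while the
fitted constants are in L/mol.

### Inner filter correction

Both the excitation and the emission beam are attenuated by whatever
absorbs in the cuvette, deflating the apparent intensity as the ligand
accumulates. The correction is the Lakowicz relation

$$F_{corr} = F_{obs} \times 10^{(A_{ex}+A_{em})/2}$$

with *decadic* absorbances (the "antilog" convention is base 10, matching
how absorbances are reported). The relation is an identity at zero
absorbance, symmetric in its two arguments, and never decreases the
intensity; the property suite checks all three. In the emulated system the
excitation-side absorbance grows from 0.08 (protein alone) to 0.42 at the
top of the titration while the emission-side absorbance is negligible, so
the correction is far from cosmetic: uncorrected data understate F at high
[Q] and bias every constant.

`correct_series()` refuses a series that mixes measured and missing
absorbances unless `pass_through = TRUE`, and refuses to silently analyse
a series with no absorbances at all — non-correction must be an explicit
choice, and it is logged.

## Quenching analysis

The Stern–Volmer relation, $F_0/F = 1 + K_{SV}[Q]$, is fitted by ordinary
least squares of $F_0/F$ on [Q]. Two conventions exist for the intercept:
the relation fixes it at 1, while plotted fits in practice are plain OLS.
The package defaults to a *free* intercept — robust to small normalisation
errors — and raises a diagnostics warning when the fitted intercept
departs from 1 by more than 5% (`intercept_tol`); `fix_intercept = TRUE`
provides the constrained variant. The [Q] = 0 point contributes its
trivial (0, 1) datum to the regression. The reported uncertainty is the
standard error of the regression slope, labelled as such.

The apparent bimolecular quenching rate constant is $K_q = K_{SV}/\tau_0$
with the unquenched lifetime $\tau_0$ supplied as a constant
(default 10⁻⁸ s, the usual biopolymer value); no lifetime fitting is
attempted. Mechanism classification combines two signatures:

| $K_{SV}$ vs T | all $K_q$ > 2×10¹⁰ | call |
|---|---|---|
| strictly decreasing | yes | static |
| strictly increasing | no | dynamic |
| monotone, contradicting $K_q$ | — | mixed |
| non-monotonic (ties included) | — | indeterminate |

A single temperature classifies on $K_q$ alone (static above the limit,
otherwise indeterminate). Monotonicity is strict: ties count as
non-monotonic rather than being resolved arbitrarily. The 2×10¹⁰
L mol⁻¹ s⁻¹ diffusion-controlled ceiling is configurable (`kq_limit`).

## Binding constant and stoichiometry

The double-logarithmic (modified Stern–Volmer) form

$$\log_{10}\frac{F_0-F}{F} = \log_{10}K_b + n\,\log_{10}[Q]$$

is fitted by unweighted OLS, matching how such linear plots are
conventionally analysed; base-10 logarithms throughout, consistent with
how "log K_b" values are tabulated. The [Q] = 0 reference is structurally
excluded (its logarithm is undefined) and any point with F ≥ F₀ is
excluded rather than clipped — a non-positive quenched fraction has no
logarithm, and clipping would bias the line. Every point is either used
or listed with its reason, so the bookkeeping is conservative by
construction.

`interpret_stoichiometry()` calls the ratio 1:round(n) when n is within
0.15 of an integer (a band wide enough to accept the usual n ≈ 1.06-style
estimates while rejecting n ≈ 0.57), and labels the affinity band of
K_b: below 10⁴ L/mol weak-to-moderate, 10⁴–10⁶ moderate-to-strong, above
10⁶ strong. Thresholds are configurable; the defaults make the standard
qualitative statements reproducible.

No multi-site or cooperative (Hill-class) models are offered, and no
direct nonlinear fit of F([Q]): the linearised form *is* the analysis this
package implements.

## Thermodynamics and binding forces

The temperature dependence of $K_b$ follows the van't Hoff relation
$\ln K_b = -\Delta H/(RT) + \Delta S/R$ (natural logarithm here, base 10
elsewhere — the mixed convention mirrors field practice), fitted by OLS of
ln K_b on 1/T with R = 8.314 J mol⁻¹ K⁻¹ and all public values in kJ.
$K_b$ is treated as dimensionless inside the logarithm (implicit 1 mol/L
standard state). With exactly two temperatures the line is exact; the
result carries a `two_point` flag instead of a meaningless R².

$\Delta G = \Delta H - T\Delta S$ at each input temperature; negative
values mark spontaneous binding. Force classification follows Ross-type
sign rules: (+ΔH, +ΔS) hydrophobic; (−ΔH, −ΔS) hydrogen bond / van der
Waals; ΔH ≈ 0 with +ΔS electrostatic; anything else mixed. "≈ 0" needs a
width: the package uses |ΔH| ≤ 4 kJ/mol (`h_tol`), roughly thermal energy
at ambient temperature and small against typical binding enthalpies;
the literature never quantifies "small", so the band is configurable.

A caution from working with published tables of this kind: printed ΔH/ΔS
values are often not exactly recoverable from the printed K_b ladder
(rounding at 2–3 significant figures propagates hard through exponentials).
The package therefore validates thermodynamics by *round-trip*: generate a
ladder from known (ΔH, ΔS), refit, and require exact recovery — plus
internal ΔG = ΔH − TΔS consistency, which holds to machine precision in
every `thermo_result`.

## Spectral modalities

Peak location underlies all three secondary analyses: the discrete maximum
inside a window is refined by the vertex of a quadratic through it and its
two neighbours, which recovers off-grid band centres of any locally
symmetric band to well within one grid step. Ties between equal maxima
break toward the lower axis value (deterministic); a maximum at the window
edge returns the grid value with a `window edge` flag; a flat window
returns its leftmost point flagged `flat region`. Shifts below a
resolution threshold — default half the grid step — are labelled `none`.
On wavelength axes a positive shift is a red shift; on the wavenumber axis
the labels invert, since lower wavenumber is lower energy.

- **Synchronous fluorescence** (scan offset Δλ): 60 nm reports the Trp
  microenvironment, 15 nm Tyr. The reported shift is between the first and
  last titration points — matching how such spectra are read — with a
  per-point trend table attached for anyone wanting a regression instead.
  The synchronous axis is the scanned excitation wavelength; the default
  window is 270–320 nm.
- **FTIR**: amide I (1600–1700 cm⁻¹, mainly C=O stretch) tracks secondary
  structure; amide II (1500–1600 cm⁻¹) is reported alongside. Windows are
  fixed to those canonical bands; spectra must cover 1500–1700 cm⁻¹ or the
  analysis refuses. The shift report is antisymmetric under swapping free
  and complexed spectra (property-tested).
- **UV-vis**: the strong band near 220 nm (backbone/α-helix; window
  210–235 nm) and the modest aromatic band near 280 nm (window
  260–300 nm). The 220 nm band's position and intensity trends across the
  titration feed `corroborate_mechanism()`: absorbance changes accompany
  static quenching (a new ground-state complex) but not dynamic quenching.
  Molar absorptivity is Beer–Lambert, ε = A/(c·l), reported for the
  highest-concentration (binding-mixture) spectrum.

## Competition analyses

Both comparative analyses operate on `log10 Kb` (regression intercepts)
rather than K_b, for numerical symmetry between enhancement and reduction.
Site assignment: a site marker that depresses log₁₀K_b by ≥ 0.2 competes
for the ligand's pocket (phenylbutazone-type probes report Sudlow site I,
diazepam-type site II). Metal ions: |Δlog₁₀K_b| ≥ 0.15 counts as
enhanced/reduced. The thresholds leave a wide margin between genuine
displacement (typical Δ ≈ 0.6) and noise-level differences (Δ ≈ 0.03–0.05)
in published albumin data; both are configurable and echoed in the output.
The package reports labels and ratios only — no mechanistic rationalisation
of *why* an ion modulates binding, and no docking.

## The synthetic generator

`generate_titration()` inverts the analysis models exactly:
F = F₀/(1 + K_SV[Q]) in Stern–Volmer mode, F = F₀/(1 + K_b[Q]ⁿ) in
double-log mode, with K_b(T) optionally derived from (ΔH, ΔS) via the
van't Hoff relation. Defaults emulate the study conditions: [Q] = 0, 10,
…, 100 µM (11 points), temperatures 303/310/318 K, λ_ex/λ_em 279/341 nm.
Noise is *multiplicative* Gaussian (relative σ, capped at 20%) — matching
fluorescence detector behaviour and keeping intensities positive at
plausible σ — and a single integer seed fixes all randomness without
disturbing the caller's RNG stream. Inner-filter distortion, when enabled,
applies the literal inverse of the correction formula with
A_ex = A_protein + ε_ligand·[Q]·l, so `correct_series()` restores the
noiseless model to machine precision; second-order inner-filter effects
are ignored, as in the analyses themselves.

`generate_spectra()` adds Gaussian-band spectra on regular grids for all
modalities, heights scaled by the same attenuation model, with programmable
band-centre drifts (synchronous red shift, amide I displacement, 220 nm
trend). Everything is deterministic given the configuration.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: wavelength-dependent detector response, baseline
drift and scatter, band asymmetry and overlapping residue contributions,
photobleaching, secondary inner-filter geometry, and ligand depletion
(bound ligand is not subtracted from [Q]; the models assume total ≈ free,
valid when ligand is in large excess over protein, as in a 2 µM protein /
0–100 µM ligand design). Exact round-trips certify the estimators and the
plumbing, not the chemistry.

## Numerical choices and test design

Problem sizes are chosen so the whole suite runs in seconds: 11-point
titrations, three temperatures, replicate counts of 30–200 for stochastic
properties, spectra of a few hundred grid points. Exact-recovery
assertions use relative tolerances of 10⁻⁸–10⁻¹⁰ (linearised OLS on
noise-free data is exact up to floating-point conditioning); qualitative
rules are asserted exactly.

One property deserves a note. The double-logarithmic intercept is an
extrapolation to log₁₀[Q] = 0 from data living around −5…−4, and the
log-ratio's noise is amplified by the reciprocal of the quenched fraction
(F₀−F)/F. With 1% intensity noise the replicate spread of log₁₀K_b is
therefore small (σ ≈ 0.06) only when every titration point is quenched
well above the noise floor (K_b ≈ 5×10⁴ on this grid), and grows
dramatically for weak binders — σ ≈ 0.26 at K_b ≈ 8.85×10³ and worse
below. The regression test checks the stable regime and asserts the
growth, rather than pretending weak-binding fits are precise.

## Known limitations

- Single-class, non-cooperative binding only; no Hill or multi-site
  models, no nonlinear F([Q]) fit.
- τ₀ is a supplied constant; no time-resolved data handling.
- No heat-capacity (curved van't Hoff) models; two temperatures are the
  minimum and three the emulated design — enthalpy from so short a ladder
  inherits all the usual leverage of exponential extrapolation.
- Peak analysis assumes locally symmetric, single-mode bands inside each
  window; no deconvolution (e.g. amide I secondary-structure fractions)
  and no baseline correction or smoothing.
- Weak-binding double-log fits are noise-sensitive (above); treat printed
  log K_b values near the bottom of the titration's dynamic range with
  corresponding caution.
- No instrument file dialects: plain CSV in, JSON out.
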
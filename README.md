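# quenchbind

Fluorescence-quenching analysis of small-molecule binding to proteins, for
spectroscopists and pharmaceutical analysts who characterise drug–serum
albumin interactions from titration data.

When a ligand quenches the intrinsic (Trp/Tyr) fluorescence of a protein
such as bovine serum albumin, a handful of linearised models extract the
whole binding picture from intensity-vs-concentration tables:

- **Inner filter correction** removes absorption artifacts:
  F<sub>corr</sub> = F<sub>obs</sub> · 10^((A<sub>ex</sub>+A<sub>em</sub>)/2).
- **Stern–Volmer analysis**: F₀/F = 1 + K<sub>SV</sub>[Q]; the apparent
  rate constant K<sub>q</sub> = K<sub>SV</sub>/τ₀ against the
  diffusion-controlled limit (2×10¹⁰ L mol⁻¹ s⁻¹) and the temperature
  trend of K<sub>SV</sub> together classify the quenching as static
  (ground-state complex) or dynamic (collisional).
- **Double-logarithmic plot**: log₁₀[(F₀−F)/F] = log₁₀K<sub>b</sub> +
  n·log₁₀[Q] gives the binding constant and stoichiometry.
- **van't Hoff thermodynamics**: ln K<sub>b</sub> = −ΔH/RT + ΔS/R, then
  ΔG = ΔH − TΔS, with Ross-type sign rules mapping (ΔH, ΔS) to the
  dominant force (hydrophobic / H-bond–van der Waals / electrostatic).
- **Secondary evidence**: synchronous-fluorescence peak shifts (Δλ = 60 nm
  → Trp, 15 nm → Tyr), FTIR amide I/II band shifts, UV-vis band trends and
  Beer–Lambert molar absorptivity.
- **Competition**: Sudlow site-marker displacement (phenylbutazone = site I,
  diazepam = site II) and metal-ion modulation of K<sub>b</sub>.

A seeded synthetic generator (`generate_titration()`, `generate_spectra()`)
produces titrations and spectra from these same forward models, so every
estimator can be validated by exact round-trip without instrument data.

## Worked example

Simulate a BSA-like experiment (2 µM protein, quencher 0–100 µM, three
temperatures) whose binding ladder follows ΔH = 133.024 kJ/mol,
ΔS = 0.487 kJ/mol/K with unit stoichiometry, then run the analysis chain:

```r
library(quenchbind)

cfg <- synthetic_config(mode = "double_log", n_sites = 1,
                        delta_h = 133.024, delta_s = 0.487)
bundle <- generate_titration(cfg)
fits <- lapply(bundle$series_by_T, fit_double_log)
fits[["303"]]
#> Double-log binding fit (303 K)
#>   log10 K_b = 2.506  (K_b = 320.7 L/mol),  n = 1
#>   R^2 = 1.0000, slope SE 3.27e-15, 10 points used, 1 excluded

thermo_pipeline(fits)
#> van't Hoff thermodynamics of binding
#>   dH = 133.024 kJ/mol (endothermic), dS = 0.4870 kJ/mol/K, R^2 = 1.0000
#>   dG(303 K) = -14.537 kJ/mol
#>   dG(310 K) = -17.946 kJ/mol
#>   dG(318 K) = -21.842 kJ/mol
#>   dominant force: hydrophobic; spontaneous at 303 K, 310 K, 318 K

interpret_stoichiometry(fits[["318"]])$stoichiometry
#> [1] "1:1"
```

Reading: the fit recovers the generating constants exactly (R² = 1; the
excluded point is the [Q] = 0 reference, whose logarithm is undefined);
positive ΔH and ΔS indicate hydrophobically driven, endothermic
association, and the negative ΔG values make binding spontaneous at all
three temperatures. The 1:1 verdict states one ligand site per protein.

Quenching-mechanism classification works the same way on a ladder of
Stern–Volmer fits:

```r
sv <- fit_stern_volmer(
  generate_titration(synthetic_config(ksv = 1.07e4,
                                      temperatures = 303))$series_by_T[[1]])
sv
#> Stern-Volmer fit (303 K, 11 points)
#>   K_SV = 1.07e+04 L/mol (slope SE 1.54e-12), K_q = 1.07e+12 L/mol/s (tau0 = 1e-08 s)
#>   intercept = 1.0000, R^2 = 1.0000
classify_mechanism(sv)$mechanism
#> [1] "static"   # K_q far above the 2e10 diffusion limit
```

`run_report()` chains every block (quenching, binding, thermodynamics,
modality, site markers, metals) over a YAML config of CSV inputs and writes
a JSON study report; see `?run_report` for the schema.

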
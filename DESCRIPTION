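Package: quenchbind
Title: Fluorescence Quenching Analysis of Ligand-Protein Binding
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of small-molecule binding to serum albumin and other
    fluorescent proteins from multi-spectroscopic titration data: inner
    filter effect correction of fluorescence intensities, Stern-Volmer
    quenching analysis with static/dynamic mechanism classification,
    double-logarithmic estimation of binding constants and stoichiometry,
    van't Hoff thermodynamics with Ross-type binding-force classification,
    synchronous fluorescence, FTIR amide-band and UV-vis feature
    extraction, site-marker competitive displacement and metal-ion
    modulation analysis, plus a seeded synthetic titration and spectra
    generator so every stage of the pipeline can be validated end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
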
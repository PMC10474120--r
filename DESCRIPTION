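Package: ppekinetics
Title: Reactivity Ratios and Microstructure of Polyphosphoester Copolymers
    from Real-Time 31P NMR Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for organocatalyzed ring-opening
    copolymerization kinetics followed by real-time 31P NMR spectroscopy.
    Converts monomer/polymer integral time series into per-monomer and total
    conversions, estimates reactivity ratios with three nonterminal models
    (Jaacks, BSL, ideal integrated), classifies gradient strength, simulates
    chain microstructure by Monte Carlo over a shared depleting monomer pool,
    and assembles polymer-level reports (degrees of polymerization, molar
    masses, compositions). Includes a synthetic kinetics generator with
    presets for binary and ternary phosphoester comonomer systems so the
    whole pipeline is testable without spectrometer data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
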
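Package: denitflux
Title: Denitrification-Driven N2O Emission Estimation for Paddy Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative chain for estimating denitrification-driven N2O
    emission from flooded paddy fields: dissolved-gas back-calculation from
    static headspace equilibration, Weiss-Price N2O solubility, air-water
    flux with pluggable gas-transfer-velocity presets, 15N isotope-pairing
    estimation of potential N2 production and N2O emission rates from
    anoxic slurry incubations, annual areal upscaling for surface soil and
    paddy water, and functional-gene diagnostics (qPCR absolute
    quantification with standard-curve gates, gene-centric metagenomic TPM
    profiling, nosZ clade I/II discrimination, and gene-by-taxon
    modularity matrices). Includes a seed-deterministic synthetic-data
    generator with ground-truth sidecars so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
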
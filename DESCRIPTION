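Package: solvatherm
Title: Volumetric and Acoustic Thermodynamics of Solutes in Mixed Aqueous Solvents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for vibrating-tube densimetry and ultrasonic
    velocimetry of amino acids and small peptides in water and in mixed
    aqueous co-solvent (e.g. ionic liquid) media. Computes apparent molar
    volumes and apparent molar isentropic compressibilities from density and
    speed-of-sound tables, extrapolates them to infinite dilution by least
    squares, derives transfer functions from water to the mixed solvent,
    fits quadratic temperature models yielding limiting apparent molar
    expansibilities and a Hepler structure-maker/breaker classification,
    and fits McMillan-Mayer pair and triplet interaction coefficients to the
    co-solvent dependence of the transfer functions. Includes a seeded
    synthetic-data generator that inverts the defining equations so every
    stage is verifiable by parameter recovery, and consistency checkers for
    published derived-property tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
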
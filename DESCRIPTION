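Package: tracerD12
Title: Tracer Diffusion Coefficients in Dense Polar and Non-Polar Solvents
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Correlates and predicts tracer (infinite-dilution) binary
    diffusion coefficients D12 of solutes in dense liquid and supercritical
    solvents, polar and non-polar alike. The model splits the friction
    coefficient of the Einstein relation into a hard-core Enskog-type term,
    built from temperature-dependent effective hard-sphere diameters and the
    binary contact radial distribution function, and an attractive
    Lennard-Jones/Stockmayer term absorbed into a single fitted coefficient.
    Two parameters per binary system (an interaction parameter k12 in the
    diameter combining rule and an attractive-friction coefficient B12) are
    estimated by Nelder-Mead minimisation of the average absolute relative
    deviation against experimental data, with automatic exclusion of state
    points where the dense-fluid correction factors lose physical meaning.
    Includes readers and writers for compound registries and measurement
    tables, a seeded synthetic-database generator for validation studies,
    subset/global performance reporting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
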
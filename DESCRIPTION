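Package: nanofield
Title: MRI Magnetic Field Design for Carbon Nanocarrier Membrane Crossing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing the MRI magnetic field that drives a
    functionalized carbon nanocarrier (a fullerene or an end-capped carbon
    nanotube) through a lipid bilayer. The package generates and parses
    constant-velocity pulling force traces of the kind produced by steered
    molecular dynamics, computes penetration work and membrane-disruption
    (RMSD slope) summaries, identifies a fixed-structure discrete transfer
    function from pulling velocity to membrane resistance force by
    prediction-error minimization, and inverts the magnetophoretic force law
    for a superparamagnetic bead to obtain the feasible set of magnetic field
    and field-gradient pairs under MRI hardware limits for a desired crossing
    time. Includes chirality arithmetic for matching a nanotube diameter to a
    fullerene end-cap and a minimal rolled-graphene coordinate builder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
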
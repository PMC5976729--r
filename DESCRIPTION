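Package: thzkerr
Title: Forward Modelling and Decomposition of the Terahertz-Induced Kerr Effect in Liquids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing terahertz-pump / optical-probe Kerr-effect
    measurements on molecular liquids. Provides multi-Debye dielectric models
    and terahertz time-domain spectroscopy transfer functions for cuvette
    geometries, frequency-domain propagation of single-cycle terahertz pulses
    through layered samples, a Langevin-type birefringence response model with
    instantaneous electronic and delayed molecular (alignment and orientation)
    terms, probe phase-shift integration with group-velocity walk-off,
    nonlinear decomposition of measured phase traces into electronic and
    molecular Kerr coefficients, molecular Kerr constants, an overdamped
    rotational Brownian-dynamics simulator of polar anisotropically
    polarizable rotors, and a synthetic-experiment generator for end-to-end
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
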
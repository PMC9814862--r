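Package: zbwater
Title: Water-Renormalized Zimm-Bragg Analysis of Helix-Coil Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Statistical-mechanical analysis of protein and polypeptide
    helix-coil transitions with an explicit water Hamiltonian that reduces
    exactly to an implicit-solvent Zimm-Bragg model. Provides the
    renormalized stability parameter in theoretical and laboratory units,
    the thermodynamic-limit order parameter (helicity degree), exact
    small-chain enumeration and transfer-matrix oracles, heat/cold
    denaturation phase classification, four-parameter nonlinear
    least-squares fitting of thermal melt curves, synthetic melt-curve
    generation, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    minpack.lm,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
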
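Package: spinorder
Title: Order Parameters and Lineshape Analysis for Membrane NMR and ESR
    Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing drug-membrane and host-guest
    interactions from one-dimensional spectra of model phospholipid
    membranes. Implements de-Pake-ing of deuterium NMR powder patterns by
    regularized non-negative inversion of an explicit orientation-averaged
    forward operator, acyl-chain quadrupolar splitting and C-D order
    parameter (S_CD) profiles with relative-fluidity statistics,
    chemical-shift-anisotropy (CSA) and isotropic-component analysis of
    31P powder lineshapes, nitroxide spin-label ESR hyperfine splittings
    and order parameters, logistic fitting of gel to liquid-crystal phase
    transitions, and continuous-variations (Job) stoichiometry plus
    simplex fitting of apparent 1:1 association constants from
    fast-exchange chemical shifts. A synthetic-spectrum generator with
    known ground truth supports validation of every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
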
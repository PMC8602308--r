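Package: tsforge
Title: Transition-State Force Fields for Enantioselectivity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and using transition-state force fields
    (TSFFs) in asymmetric catalysis. Fits molecular-mechanics parameters to
    quantum-chemistry-style reference data (geometries, Hessians, partial
    charges) with a quantum-guided penalty function, assembles competing
    diastereomeric transition-state structures from fragment libraries,
    performs seeded Monte-Carlo torsional conformational searches, converts
    Boltzmann-averaged transition-state ensemble energies into enantiomeric
    ratios and excesses, and proofreads experimental stereochemical
    assignments by flagging confident sign disagreements between predicted
    and reported configurations. Includes a synthetic-fixture generator so
    the whole pipeline can be exercised without quantum-chemical input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
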
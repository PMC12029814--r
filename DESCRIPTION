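Package: cdbind
Title: Host-Guest Binding Analysis for Cyclodextrin Inclusion Complexes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of 1:1 host-guest complexation, built
    around the exact mass-action binding isotherm. Implements
    continuous-variation (Job plot) stoichiometry analysis and global
    fitting of association constants from fast-exchange NMR chemical-shift
    perturbations, simulation and fitting of isothermal titration
    calorimetry (ITC) thermograms under the independent-sites model with
    perfusion-cell displacement bookkeeping, and the thermodynamic linkage
    relations connecting the association constant, Gibbs energy, enthalpy
    and entropy. Includes seeded synthetic-data generators that emulate
    standard continuous-variation and ITC experimental designs, so every
    fitting stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
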
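Package: bindspec
Title: Spectroscopic Analysis of Protein-Ligand Binding by Fluorescence
    Quenching and Circular Dichroism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying small-molecule binding to proteins from
    steady-state spectroscopy. Implements Stern-Volmer analysis of
    tryptophan fluorescence quenching titrations (classical, segmented
    two-regime, and Lehrer accessible-fraction models), inner-filter
    correction, quenching-mechanism classification from the bimolecular
    rate constant, conversion of circular dichroism signals to mean
    residue ellipticity, constrained basis-set estimation of secondary
    structure fractions, and two-state fits of thermal denaturation
    curves yielding unfolding midpoints. Includes seeded mechanistic
    generators of synthetic titrations, spectra, and melt curves for
    method validation and parameter-recovery studies, plus a small
    config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
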
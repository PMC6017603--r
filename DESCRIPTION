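Package: flexbind
Title: Conformational Ensemble Flexibility and Ligand Binding Propensity
    with Steady-State SPR Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise the conformational flexibility of a
    protein ensemble and relate it to small-molecule binding measured by
    surface plasmon resonance (SPR).  Provides trajectory geometry
    (Kabsch superposition, RMSD, RMSF, Shrake-Rupley solvent-accessible
    surface area, leader-style conformational clustering), an
    inverse-docking binding-propensity workflow that scores what fraction
    of ensemble conformations is competent to bind a ligand, steady-state
    SPR analysis (blank subtraction, equilibrium extraction, one-site
    Langmuir fits with Scatchard initialisation, competition metrics and
    RU-to-surface-density conversion), small-n exact permutation
    correlation between pocket availability and equilibrium binding, and
    synthetic-data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
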
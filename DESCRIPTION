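Package: wins7
Title: Structural Analysis of the WDR5 WIN-S7 Pocket Switch and ITC Binding Thermodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative structural analysis of WDR5 beta-propeller
    complexes with WIN-motif peptides and small molecules, centred on the
    Tyr191 rotamer switch that opens and closes the S7 subsite. Provides a
    coordinate data model over PDB/mmCIF files, Kabsch rigid-body
    superposition, an aromatic side-chain rotation metric, a typed
    protein-peptide interaction fingerprint (hydrogen bonds, salt bridges,
    cation-pi, van der Waals, ordered-water bridges), a grid-based pocket
    openness classifier, and a single-site isothermal titration calorimetry
    forward model, fitter, and thermodynamic decomposition. Includes synthetic
    fixture generators so the full analysis surface is testable without any
    deposited structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
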
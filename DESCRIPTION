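Package: dimerlab
Title: Quantitative Characterization of Intertwined Protein Homodimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for small intertwined homodimeric proteins
    characterized by solution NMR, built around the lambda bacteriophage Orf63
    lytic developmental protein. Provides deterministic Shrake-Rupley
    solvent-accessible surface areas and PISA-style dimer-interface
    decomposition with salt-bridge and hydrogen-bond detection; Kabsch
    superposition, NMR-ensemble precision statistics, dihedral-window
    secondary-structure assignment and inter-helix geometry; weighted amide
    chemical-shift-perturbation (CSP) mapping of ligand binding; nonlinear fits
    of fluorescence-polarization binding isotherms and two-state thermal and
    chemical denaturation curves; per-column conservation profiling of homolog
    alignments; and seeded synthetic-data generators with recorded ground truth
    so that every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
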
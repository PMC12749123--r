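Package: memdefect
Title: Lipid Packing-Defect and Protein-Membrane Interaction Analysis for
    Planar Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Grid-based detection and quantification of lipid packing
    defects in planar bilayer coordinate files (GRO, multi-model PDB):
    headgroup projection onto a 0.1 nm grid, merging of defect cells within
    0.3 nm into defects, deep/shallow classification against a plane 1
    Angstrom below the glycerol region, per-frame and trajectory statistics,
    and an exponential fit of the defect-size distribution yielding the
    defect size constant A0.  Also counts protein-membrane hydrogen bonds
    with a geometric donor-acceptor criterion and computes cutoff-truncated
    Coulomb and Lennard-Jones interaction energies decomposed by residue
    group and lipid species.  A deterministic synthetic bilayer generator
    with controllable carved defects and sterol condensation provides
    ground-truth test systems, and a command-line interface ties the
    pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
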
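Package: mtring
Title: Per-Residue Interaction Energetics of Microtubule Rings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds idealized 13-protofilament B-lattice microtubule rings
    (including the seam and periodic images) from a tubulin-dimer template,
    scores every lateral and longitudinal dimer-dimer interface with an
    MM/GBSA-style interaction energy (Lennard-Jones, Coulomb, generalized
    Born polar solvation with OBC-II radii, and Shrake-Rupley surface-area
    non-polar solvation) decomposed per residue, and aggregates the
    per-subsystem tables into per-ring totals, ligand/receptor subunit
    matrices, domain tables, nucleotide-state difference maps, radial and
    tangential energy profiles across the longitudinal interface, and ring
    energy diagrams. Also provides trajectory geometry observables
    (perpendicular ring diameters and backbone RMSD) and seeded
    synthetic-data generators (toy parameterized dimers, ovalized ring
    trajectories, mock per-residue energy tables with planted ground truth)
    so that every stage can be exercised without external inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
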
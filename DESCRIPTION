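Package: abscan
Title: Computational Alanine Scanning of Protein-Ligand Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systematic in silico alanine-scanning mutagenesis of the residues
    lining a protein-ligand binding site. Every binding-site residue is
    truncated to alanine, the intermolecular interaction energy of the wild
    type and of each mutant is evaluated with an AutoDock4-style semi-empirical
    force field (Lennard-Jones 12-6, distance-only 12-10 hydrogen bond,
    screened Coulomb electrostatics with a distance-dependent dielectric, and a
    Gaussian desolvation term), and per-residue ddG contributions are ranked to
    nominate candidate loss-of-function mutations. Includes PDB/PDBQT readers
    and writers, receptor preparation (AutoDock atom typing, polar-hydrogen
    completion, Gasteiger PEOE partial charges, united-atom merging), a
    synthetic complex generator for testing, CSV/JSON/PyMOL reporting, and a
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
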
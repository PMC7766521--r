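Package: deutbind
Title: Deuterium Isotope Effects on Receptor-Ligand Hydrogen Bonding and
    Binding Thermodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying how non-selective deuteration of
    exchangeable X-H bonds (X = N, O, S) modulates ligand binding at a
    G-protein coupled receptor, exercised on histamine at the H2 receptor.
    Provides a light-weight structure/trajectory data model with PDB and XYZ
    readers and writers, exact internal-coordinate measurements, synthetic
    generators for solvated ligands, binding-pocket cluster models and
    multi-frame trajectories with prescribed conformer populations and
    hydrogen-bond occupancy schedules, gauche/trans conformer classification
    and k-medoids clustering, radial distribution functions with finite-system
    edge correction, coordination numbers, geometric hydrogen-bond detection
    and contact occupancy statistics, the empirical 2.3 percent bond
    contraction emulating nuclear quantum effects of deuteration, binding-site
    cluster and solvent-shell extraction, the H/D thermodynamic binding cycle,
    affinity unit conversions (pKi, pIC50 via the Cheng-Prusoff relation) and
    microspecies protonation fractions, and per-residue MM-GBSA decomposition
    bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
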
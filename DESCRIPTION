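Package: popshift
Title: Ensemble Rescoring, Free-Energy Spectra and Side-Chain Rotamer
    Population Shifts for Protein-Ligand Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating small-molecule binding modes in
    macromolecular complexes with a semi-empirical pairwise scoring
    function of the AutoDock4 family: direct rescoring of fixed poses,
    local refinement, and multi-start docking on precomputed affinity
    grids with trilinear interpolation.  Conformational ensembles
    (multi-model PDB trajectories) can be rescored snapshot-by-snapshot
    into free-energy spectra, yielding the most probable binding free
    energy and an inhibition constant via the Boltzmann relation
    Ki = exp(dG/RT).  Side-chain chi1-chi4 dihedral series are extracted,
    summarized as circular histograms, and clustered with a periodic
    dihedral RMSD metric to detect ligand-induced rotamer population
    shifts.  Includes synthetic generators (toy pockets, noisy ensembles,
    circular-mixture rotamer trajectories) so the whole pipeline is
    testable without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
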
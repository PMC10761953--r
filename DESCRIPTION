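Package: allopath
Title: Perturbation Response Scanning and Allosteric Pathway Analysis for Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for probing allosteric communication in proteins at
    coarse-grained resolution. Builds anisotropic network model (ANM)
    Hessians and their pseudo-inverse covariances from C-alpha coordinates,
    or estimates covariances from superposed conformational ensembles;
    performs perturbation response scanning (PRS) with Fibonacci-sphere
    isotropic force sampling propagated through linear response theory;
    extracts shortest allosteric pathways between binding-site and
    active-site residues over PRS-weighted residue contact graphs with
    deterministic Dijkstra tie-breaking, and scores mediator residues.
    Also provides trajectory stability metrics (Kabsch RMSD, RMSF, radius
    of gyration, Shrake-Rupley solvent-accessible surface area, geometric
    hydrogen-bond counting, k-means clustering with representative frames)
    and the MM-PBSA component-aggregation identities, plus synthetic
    structure and ensemble generators with planted ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'allopath-package.R'
    'structure-io.R'
    'elastic-network.R'
    'prs.R'
    'pathways.R'
    'traj-metrics.R'
    'energetics.R'
    'fixtures.R'
    'pipeline.R'
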
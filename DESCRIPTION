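Package: aftopo
Title: Topological Phase-Singularity Analysis and Virtual Ablation for Reentrant Atrial Arrhythmia Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the topological analysis of reentry-driven atrial
    fibrillation in surface simulations. Detects phase singularities by
    counting signed phase jumps (discrete topological charge) on
    subsampled triangulated meshes, including synthetic nodes inside
    anatomical cavities so that anatomical and functional reentries are
    handled identically. Tracks singularities through space and time,
    computes index-theorem adherence metrics, singularity-count maps and
    bivariate Moran's I spatial similarity, and plans virtual ablation
    lines (phase-aware heuristic, geodesic straight, and random control
    strategies) that pair opposite-chirality singularities at minimum
    total cost. A desk-scale electrophysiology module (Courtemanche
    human atrial cell with atrial-fibrillation and fibrotic remodeling,
    1D cable, 2D monodomain sheet with phase-distribution reentry
    induction) generates all inputs synthetically.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    tibble,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
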
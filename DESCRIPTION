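Package: tomopack
Title: Particle Packing Analysis for Cryo-Electron Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Localizes quasi-spherical macromolecular complexes in
    cryo-electron tomograms by rotation-free spherical-template matching
    with Crowther-criterion low-pass filtering, aligns and averages
    subvolumes around the detected particles without imposing symmetry,
    pools transform-registered nearest-neighbor point clouds, and fits
    hard-sphere lattice models (hexagonal close packing, cubic close
    packing, body-centered cubic) to the clustered neighbor centers by
    diameter-scanned nearest-correspondence RMSD minimization. Also
    provides membrane-stack line-scan densitometry with autocorrelation
    layer measurement, envelope-invagination counting statistics, and a
    ground-truthed synthetic-scene generator (jittered lattices, rendered
    volumes with optional missing wedge, layered membrane phantoms) for
    validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
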
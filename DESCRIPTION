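Package: phunlattice
Title: Analysis of 2D Crystalline Phage-Nucleus Lattices from Cryo-EM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational analysis of two-dimensional
    crystalline protein lattices such as the phage-nucleus enclosure (PhuN)
    shell, imaged by limited-tilt cryo-electron microscopy. Simulates
    plane-group (p1/p2/p4) lattice micrographs, tilt-limited projections and
    missing-cone volumes with known ground truth; indexes lattice images by
    autocorrelation peak analysis and classifies plane-group symmetry; computes
    global and directional Fourier shell correlation to quantify preferred
    orientation; builds an optical transfer function from directional FSC and
    restores missing-cone volumes by entropy-regularized deconvolution; and
    provides structural comparison metrics (Kabsch superposition RMSD,
    rigid-body fitting with masked correlation, lattice expansion, channel
    geometry, inter-assembly rotation, interface contacts, sequence mass).
    Includes MRC2014 volume/image I/O, PDB/mmCIF model reading and a
    STAR-like particle table format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    withr
Config/testthat/edition: 3
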
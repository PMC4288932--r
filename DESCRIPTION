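Package: perfusim
Title: Perfusion Flow and Shear-Driven Cellular Growth in Voxelized Porous Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Microscale simulation of culture-medium perfusion through
    additive-manufactured porous scaffolds and of the shear-stress-regulated
    growth of bone precursor cells on strut surfaces. Provides octahedral
    unit-cell lattice generation with reproducible vertex randomization,
    slicing into laser melt points and spherical-kernel voxelization with
    porosity calibration; a fraction-field incompressible Navier-Stokes
    projection solver on a staggered voxel grid with a liquid-fraction
    momentum sink; local shear-stress evaluation at growth interfaces; a
    shear-windowed linear growth law coupled back into the flow; and
    statistical characterization of the resulting shear and growth fields
    (log-binned histograms, distribution moments, pressure drop, Darcy
    permeability, growth volume fraction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
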
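Package: FractureTwin
Title: Digital-Twin Biomechanics for Fracture-Fixation Revision Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reproducible pipeline for comparing fracture-fixation
    treatment variants on idealized bone-implant constructs: parametric
    synthetic CT generation with ground-truth label maps, threshold
    segmentation, voxel-based tetrahedral meshing with named boundary
    node sets, CT greyvalue-to-modulus material mapping, static linear
    elastic finite element solution under peak joint loads, healing
    window evaluation from octahedral shear and volumetric strain,
    implant von Mises stress comparison, and rigid-body range-of-motion
    impingement sweeps for joint realignment scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    RNifti,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
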
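Package: tevgsim
Title: Virtual Implantation of Tissue-Engineered Vascular Grafts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how surgical placement imprecision of a
    tissue-engineered vascular graft (TEVG) in the aorta affects postoperative
    shape and hemodynamics. Generates parametric synthetic aortic anatomies
    (ascending aorta, arch with supra-aortic branches, descending aorta) as
    quadrilateral shell meshes, performs virtual clamp placement, resection and
    graft design, applies controlled translation/rotation/size deviations, and
    simulates the end-to-end anastomosis with a hyperelastic (Yeoh) membrane
    finite-element model in which paired suture nodes are coupled by dummy-node
    multi-point constraints. Hemodynamic consequences (peak systolic pressure
    drop and time-averaged wall shear stress) are evaluated with a reduced-order
    Poiseuille resistance network driven by a pulsatile inflow and three-element
    Windkessel outlets. Deviation sweeps produce tolerance maps of allowable
    graft placement error, and rigid-registration shape metrics (Hausdorff and
    mean surface distance, anatomical-frame deviation decomposition) quantify
    shape agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
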
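Package: lungtree
Title: Anatomically Plausible Bronchial Tree Generation, Airway Surface
    Modelling and Broncho-Constriction Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building patient-scale models of the human bronchial
    tree from a lung-volume mask and a short seed airway centerline. The
    package grows an extended bifurcating airway tree by a volume-filling
    algorithm driven by uniform point sampling of the lung subvolumes,
    computes per-generation Gaussian spatial probability maps on the image
    grid, assigns branch diameters by symmetric power law or by
    diameter/angle branching relations, samples oriented tubular point
    clouds and reconstructs watertight airway surfaces, simulates
    broncho-constriction by constrained Laplacian mesh contraction with
    shape-diameter-function monitoring, and validates generated trees with
    Strahler/Horsfield morphometry (branching, diameter and length ratios,
    branching angles, terminal counts). Includes a synthetic two-lung
    phantom generator so the full pipeline runs without external data.
    Reads and writes MetaImage (MHD/raw), NIfTI-1, OBJ, PLY and STL files
    plus a JSON centerline-graph schema.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
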
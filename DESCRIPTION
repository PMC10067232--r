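Package: plateforge
Title: Patient-Specific Reconstruction-Plate Template Design from CT-Derived Bone Surfaces
Version: 0.1.0
Authors@R:
    person("plateforge", "developers", email = "plateforge@example.org", role = c("aut", "cre"))
Description: Semi-automatic design of curved, chain-of-units fixation-plate
    templates for fracture surgery planning. Provides threshold segmentation
    and fragment splitting of volumetric images, isosurface extraction to
    triangle meshes, virtual fracture reduction (mirroring and landmark-based
    rigid alignment), construction of smoothed on-surface plate paths from
    operator-selected anchor points (with chord bridging over reduction gaps
    and a mid-line crop/lengthen rule matching path length to whole plate
    units), penetration-safe posing of parametric plate units along the path,
    and export of print-ready STL templates. Includes a synthetic-phantom
    generator (spheres, tori, swept tubes, voxel phantoms, simulated
    fractures with known ground truth) so the entire pipeline is testable
    without patient data. All coordinates are millimetres.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
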
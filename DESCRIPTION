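Package: noseforge
Title: Statistical Shape Model Driven Design of Nasal Prostheses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semi-automated computer-aided design of nasal prostheses from a
    defect-bearing 3D face scan. A PCA morphable face model, optionally
    augmented with smooth Gaussian-process deformation modes, is fitted to
    the defect-masked scan to reconstruct the missing nose. The reconstructed
    nose model is converted into a prosthesis model and a two-part
    3D-printable mold through a parameterized geometric protocol (border
    blending, wall solidification, boolean subtraction, nostril sculpting,
    flanged mold shells). Includes a mesh geometry kernel (signed distance,
    offsets, booleans via isosurface extraction), STL/PLY/OBJ input and
    output, and a synthetic face-population generator with simulated
    rhinectomy defects for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
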
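Package: icpps
Title: Sparse Point-to-Bone Registration with Axis-Constrained Perturbation Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Rigid registration of sparse, noisy surface sample points (such as
    A-mode ultrasound bone digitizations) to a known triangulated bone surface
    model, for computer-aided orthopedic surgery. Implements a four-step
    procedure: coarse point-to-point pre-registration on labeled anatomical
    areas, iterative closest point (ICP) refinement, an axis-constrained
    perturbation grid search that escapes the axial local minima created by
    cylinder-like long bones, and a perturbation-to-ICP feedback loop. Includes
    STL surface I/O, a procedural labeled synthetic femur generator, and a
    Monte-Carlo simulation framework that quantifies bone-to-bone registration
    error as a function of point count and per-point localization error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
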
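Package: adaptherm
Title: Adaptive 3D Bioheat Simulation from Rotated MR Thermometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs volumetric heat distributions during MR-guided
    thermal ablation from 2D temperature maps acquired on planes rotated
    around the applicator axis. Temperature maps are compressed into
    noise-robust isotherms via a monotone shortest-path filter; a 3D Pennes
    bioheat equation reduced to a diffusion process (no explicit
    treatment-specific heat-source term) is advanced by a Crank-Nicolson
    alternating-direction-implicit scheme; thermal diffusivity and the
    peak source temperature are re-estimated for every incoming image by
    bounded Levenberg-Marquardt least squares. Includes a synthetic phantom
    generator with known ground truth, necrosis thresholding, Dice and
    standard-error evaluation, and a robustness-configuration harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
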
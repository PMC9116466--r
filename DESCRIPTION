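Package: osteosim
Title: Optical Bone Densitometry by Voxel Monte Carlo Simulation and
    Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end simulation pipeline for near-infrared optical bone
    densitometry of the ultradistal radius. Generates synthetic trabecular
    microarchitecture with a Turing activator-inhibitor reaction-diffusion
    model, assembles layered voxel tissue models (dermis, subcutaneous
    tissue, cortical bone, trabecular bone, marrow) with randomized
    structural and optical properties, simulates steady-state photon-packet
    transport with a voxel Monte Carlo engine (hop-drop-spin with Fresnel
    refraction and Henyey-Greenstein scattering), extracts spatially
    resolved diffuse-light features in backward, forward and lateral
    directions, and predicts areal bone mineral density with cross-validated
    regression models (ridge, support vector, random forest, gradient tree
    boosting). Includes standard trabecular histomorphometry measures and
    Bland-Altman agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    e1071,
    ranger,
    xgboost,
    yaml,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
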
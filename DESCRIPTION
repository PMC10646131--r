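Package: kneetrack
Title: Tibiofemoral Kinematics from Bone Meshes and Rigid-Body Pose Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric analysis of tibiofemoral kinematics from triangulated
    bone or implant surface meshes and per-frame rigid-body poses, as produced
    by fluoroscopic 3D-model-to-2D-image registration. Constructs anatomic
    axes and reference frames, simulates the tibial resection plane with
    varus-valgus balancing, tracks femoral condylar anterior-posterior
    positions by the lowest-point method, derives tibial internal-external
    rotation profiles and arc-of-extension changes, and performs the cohort
    statistics (Welch comparisons, chi-square tests, and noncentral-t power
    and minimum-detectable-difference analysis). Includes a parametric
    synthetic knee and trajectory generator with a registration-noise model
    so every stage can be validated against closed-form ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
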
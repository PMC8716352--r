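Package: cbctnav
Title: Fiducial Calibration, Trajectory Planning and Targeting Evaluation
    for CBCT-Guided Robotic Needle Placement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Navigation core for robot-assisted percutaneous needle
    placement under cone-beam CT guidance. Provides a synthetic phantom
    generator with ground truth (calibration tool with four hollow
    fiducial spheres at pairwise-unique distances, plus soft-tissue
    target lesions), 3D blob detection with subvoxel centroids,
    correspondence-free fiducial matching by distance signature,
    closed-form rigid robot-to-image registration with fiducial
    registration error, needle trajectory planning under gantry
    angulation limits, the angular/absolute/longitudinal targeting-error
    triple, study-level summaries with one-way ANOVA, and a minimal
    big-endian binary message protocol for image-guided-therapy links.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
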
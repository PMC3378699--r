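Package: mtpm
Title: Tissue Phase Mapping of Murine Cardiac Phase-Contrast MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction and analysis of myocardial tissue phase mapping
    (phase-contrast cine MRI) data from the mouse heart. Converts
    motion-compensated plus x/y/z motion-encoded k-space or complex image
    stacks into calibrated voxelwise velocity maps (zero-filling, radial
    Butterworth apodization, phase-difference velocity encoding, static-
    reference background phase correction), transforms them to radial,
    circumferential and longitudinal components about the left-ventricular
    center of mass with bulk-motion correction, and derives AHA 16-segment
    regional time courses, epicardial/endocardial compartment analysis,
    twist and torsion, and method-agreement statistics (Bland-Altman,
    slope-versus-one regression, angular synchrony correlation maps). A
    synthetic cine phantom with analytically known kinematics supports
    validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
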
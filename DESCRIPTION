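Package: decbct
Title: Dual-Energy CBCT Hounsfield-Unit Calibration and Cross-Modality
    Voxel-Value Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates dental dual-energy cone-beam CT (CBCT) voxel values
    to Hounsfield units from paired low/high-kVp acquisitions of a
    hydroxyapatite calibration phantom, and quantifies cross-modality
    voxel-value agreement against multidetector CT (MDCT). Provides a
    world-coordinate voxel-grid model with rigid transforms and trilinear
    resampling, a synthetic dual-energy phantom and jaw-scene generator with
    known ground truth, total-least-squares density-line calibration with an
    affine HU map, multiresolution intensity-based rigid registration with
    inverse-transformed cylindrical regions of interest, identity-line
    deviation-band reports, and Bland-Altman percent-difference analysis with
    confidence intervals of the limits of agreement. Includes a minimal
    single-frame CT DICOM series reader/writer and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
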
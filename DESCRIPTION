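Package: clawxrd
Title: Claw Keratin X-ray Diffraction Cancer Screening Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of two-dimensional X-ray diffraction
    (XRD) patterns of claw keratin shavings for non-invasive cancer
    screening. Provides a synthetic cohort generator for fiber-diffraction
    detector images (keratin arcs at 0.51 nm and 0.98 nm, amorphous
    background, primary-beam spot, hot pixels, Poisson counting noise),
    detector-geometry conversions, silver behenate scale calibration,
    centering/cropping/rotation preprocessing with hot-pixel repair and
    intensity standardization, Fourier-series feature extraction from radial
    and circular intensity profiles, a patient-grouped cross-validated
    random-forest classifier with sample-to-patient probability aggregation,
    and ROC/sensitivity/specificity/balanced-accuracy reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    jsonlite,
    ranger
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
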
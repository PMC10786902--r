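Package: lidmetrics
Title: Automated Eyelid Morphometry from Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Periocular morphometry from binary segmentation masks of
    face-crop photographs. Computes margin-reflex distances (MRD1, MRD2),
    corner-corrected digital eyelid lengths, corneal boundary length and a
    fiducial-marker millimetre calibration; builds 360-degree radial contour
    profiles about the intercanthal reference frame and detects eyelid
    abnormalities against partition-wise normative ranges; includes
    method-comparison statistics (intraclass correlation with qualitative
    bands, Bland-Altman limits of agreement), a pluggable segmentation
    backend contract scored by mean intersection-over-union, and a synthetic
    eyelid-scene generator with pixel-exact ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
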
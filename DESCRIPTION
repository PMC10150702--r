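Package: octmargin
Title: Residual Tumor Detection from Intraoperative Optical Coherence
    Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for residual brain-tumor detection at the
    resection margin with microscope-integrated optical coherence tomography
    (OCT). Provides a physics-based synthetic OCT cohort generator
    (single-scattering exponential depth decay, multiplicative speckle,
    system roll-off and focus sensitivity, surface topography, artifact
    injection), the preprocessing chain (depth-sensitivity compensation,
    surface detection and flattening, en-face projection, patch extraction,
    scan quality control), depth-resolved optical-property extraction by
    log-linear least squares (attenuation coefficient, backscattered
    intensity, fit determination coefficient), a rule-based five-criterion
    visual classifier, leave-one-patient-out linear support-vector-machine
    evaluation over classification tasks, diagnostic-metric and contingency
    arithmetic, and small dense-network training protocols for patch
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
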
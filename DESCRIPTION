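Package: conelung
Title: Truncated-Cone MicroCT Lung Volumetry for Rodents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast geometrical estimation of mouse lung volume from thoracic
    microCT. Thoracic volume is computed from three anatomical landmark
    distances (carina-level small base, diaphragm-level large base, and
    carina-to-diaphragm height) via a conical-frustum model, then calibrated
    against manually delineated lung volume by linear regression to yield a
    theoretical lung volume. The package ships the complete supporting
    pipeline: Hounsfield-unit calibration from air/water phantom VOIs,
    aerated-lung threshold segmentation, emulated manual delineation with
    signed-distance inter-slice contour interpolation, and a validation
    battery (volume ratios, Bland-Altman agreement, Gage R&R variance
    components, 5 percent-deviation sensitivity/specificity). A synthetic
    mouse-thorax phantom generator with exact ground-truth manifests makes
    every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
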
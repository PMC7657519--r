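Package: antromap
Title: Validation of Cine-MRI Gastric Antral Motility Mapping Against Perfused Manometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify gastric antral motility from dynamic (cine) MRI by
    spatio-temporal motility mapping -- respiratory motion correction, lumen contour
    propagation, perpendicular diameter measurement along the antral axis, and
    per-block area-under-the-curve (AUC) summaries in mm x s -- and to validate the
    imaging read-out against simultaneous water-perfused manometry (AUC in mmHg x s).
    Includes a paired-modality phantom simulator driven by a common peristaltic
    wall-motion model with a two-regime (intrabolus hydrodynamic / mucosal contact)
    pressure transduction, manometry signal processing (respiration filtering,
    rolling-percentile baseline correction, block segmentation), and the statistical
    machinery used for validation: Pearson correlation of per-subject and pooled
    block AUCs, mixed-effects regression with natural-spline conditional means and
    likelihood-ratio tests for non-linearity, and power simulations for correlation
    estimates under within-modality autocorrelation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    rlang,
    RNifti,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
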
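Package: calcquant
Title: Threshold-Based Volumetry and Agreement Analysis of Peripheral
    Vascular Calcifications in Paired CT and MR Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies peripheral vascular calcification from paired
    computed-tomography angiography (CTA) and proton-density in-phase MR
    volumes. Provides NIfTI volume input/output with tricubic resampling to
    isotropic resolution, modality-specific threshold segmentation inside
    cylindrical vessel-segment regions of interest (a fixed Hounsfield-unit
    cutoff for CT; a mean minus k standard deviations rule for MR), severity
    classification, thin-slab minimum/maximum intensity projections, and the
    full agreement-statistics layer (Pearson correlation with Fisher-z
    confidence intervals, absolute-agreement intraclass correlation,
    Bland-Altman bias and limits of agreement, weighted Cohen's kappa).
    A synthetic phantom generator renders paired CT/MR exams with known
    ground-truth deposit volumes, modelling CT blooming as point-spread
    blurring and MR surface-water signal as core erosion, and a desk-scale
    stack-of-stars k-space simulator demonstrates how the partition-inner
    acquisition ordering suppresses motion ghosts that the view-inner
    ordering produces.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
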
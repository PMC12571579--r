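Package: ihcsens
Title: Analytic Sensitivity, Dynamic Range and Diagnostic Accuracy of
    Calibrated Immunohistochemistry Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating immunohistochemistry (IHC) assays with
    bead-based calibrators. Quantifies stained calibrator microbead images
    (greyscale conversion, circle Hough segmentation, DAB chromogen dot-product
    intensities) into per-spot stain summaries; estimates each laboratory's
    lower limit of detection (LOD) as the analyte concentration whose fitted
    log-regression intensity equals the negative-control mean plus three
    standard deviations; computes per-core consensus HER2 scores with and
    without the ultralow (0.5) category; measures assay dynamic range as the
    regression slope of aggregate score on LOD with slope t-tests; and models
    diagnostic accuracy and treatment-decision concordance against in situ
    hybridisation or LOD-defined gold standards, with exact Clopper-Pearson
    confidence intervals. A synthetic-data module generates calibrator images,
    laboratory cohorts, tissue-microarray score matrices and ISH tables with
    known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
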
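Package: octascreen
Title: OCT-A Feature Extraction and SVM Screening for Cognitive Impairment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies retinal microvasculature from optical coherence
    tomography angiography (OCT-A) images and screens for mild cognitive
    impairment and Alzheimer's disease with kernel support vector machines.
    Implements foveal avascular zone (FAZ) segmentation with area, centroid
    and boundary from binary image moments, five-sector vessel density on an
    ETDRS-like grid, a reduced-vessel-density-area (RVDA) feature, range-filter
    histogram features (central intensity and full width at half maximum),
    retinal thickness from B-scan intensity profiles, and a one- and
    two-feature SVM model search evaluated with confusion-matrix metrics and
    ROC/AUC. A seeded phantom generator provides en-face angiograms, B-scans
    and labelled cohorts with known ground truth so the whole pipeline is
    testable without clinical data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    kernlab,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    png,
    tiff,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
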
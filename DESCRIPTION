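Package: breastdwi
Title: Breast Fibroglandular Tissue Segmentation and ADC Analysis for
    Diffusion-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how fatty-tissue partial volume drives apparent
    diffusion coefficient (ADC) measurements in the breast. Provides a
    synthetic axial breast MRI generator with known ground truth (T1-weighted
    volumes, diffusion-weighted signals, bias fields, misaligned ADC grids),
    fuzzy C-means multiplicative bias-field correction, landmark-based breast
    segmentation with a V-shape chest cut and slice propagation, k-means
    fibroglandular/fat tissue splitting with percent-density computation,
    affine coregistration by normalized mutual information, four
    region-of-interest ADC summaries (whole breast, whole fibroglandular
    tissue, central slice, small homogeneous ROI) with validity filtering and
    32-bin histograms, and cohort-level statistics (Pearson correlation,
    intraclass correlation, paired and stratified t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    ggplot2,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
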
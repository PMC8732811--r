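Package: petresponse
Title: Quantitative FDG-PET Response Assessment with EORTC, PERCIST and
    imPERCIST Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative response assessment of solid tumors on
    serial FDG-PET, aimed at immune-checkpoint-inhibitor therapy monitoring
    across scanners. Extracts lesion metrics (SUV_max, SUV_mean, SUV_peak,
    SUL_peak, metabolic tumor volume at a 40% isocontour, total lesion
    glycolysis) from voxel grids, emulates cross-scanner SUV harmonization by
    Gaussian filtering at a scanner-specific FWHM, classifies baseline to
    follow-up change as CMR/PMR/SMD/PMD under the EORTC, PERCIST and
    imPERCIST rule sets, and compares criteria via weighted Cohen's kappa,
    percent agreement, Kaplan-Meier curves and log-rank tests. Includes a
    synthetic phantom and cohort generator so the full pipeline is testable
    without patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
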
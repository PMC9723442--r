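Package: sbrteval
Title: Dosimetric and Radiobiological Evaluation of Stereotactic Body
    Radiotherapy Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and comparing stereotactic body
    radiotherapy (SBRT) treatment plans for bilateral lung lesions.
    Computes cumulative dose-volume histograms and the usual
    dose-volume metrics (Dmax, Dmean, Vx, Dxcc, coverage) from voxel
    dose grids and structure masks, target-centric plan-quality
    indices (conformity, new conformity, homogeneity, gradient,
    prescription isodose line), fractionation-corrected generalized
    equivalent uniform dose (gEUD) via the linear-quadratic model,
    dose-constraint audits, and paired single-plan versus
    double-plan cohort comparisons. Includes a seeded synthetic
    bilateral-lung phantom cohort generator so the full pipeline runs
    without protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
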
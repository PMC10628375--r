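Package: gridquant
Title: Grid-Based Quantification of Tumor-Stroma Ratio and Stromal
    Tumor-Infiltrating Lymphocytes on H&E Microphotographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an inscribed square-grid point-counting method for
    quantifying the tumor-stroma ratio (TSR) and stromal tumor-infiltrating
    lymphocytes (sTIL) on circular-field microphotographs of H&E-stained
    invasive breast carcinoma. Fits the circular field of view, inscribes a
    10x10 equal-cell grid by the Pythagorean construction a = d/sqrt(2),
    classifies each grid cell as tumor-, stroma- or lymphocyte-predominant
    via color deconvolution and blob detection, and computes per-field
    percentages, case-level tier scores, and inter-observer agreement
    (Cohen's kappa). Ships a seeded synthetic-field generator with full
    ground truth, so the whole pipeline is testable without external data.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
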
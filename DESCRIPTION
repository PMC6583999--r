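Package: acefrac
Title: Three-Dimensional CT Measurement of Articular Fracture Displacement
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies displacement of articular (acetabular) fractures from
    3D surface models. Builds a mirrored contralateral template, performs
    virtual anatomical reduction of fracture fragments by rigid (ICP)
    registration, decomposes per-point fracture-line displacement into a 3D
    step-off (perpendicular to the articular surface) and a 3D gap (along
    it), and computes a projected total-gap-area metric in a standardized
    landmark-defined view. Includes CT-based reduction grading (Matta and
    3D-CT criteria), a 2D slice-measurement emulator, agreement statistics
    (exact Wilcoxon signed-rank, Spearman's rho, ICC(A,1)), and a synthetic
    fractured-cup phantom generator with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    RANN,
    polyclip,
    RNifti,
    jsonlite,
    yaml,
    digest,
    generics,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
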
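Package: hicomp
Title: Differential A/B Compartment Analysis for Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes A/B compartment scores from cis Hi-C contact maps by
    observed/expected normalization, correlation-matrix principal component
    analysis with covariate-driven component selection and sign orientation,
    quantile-normalizes scores across samples and replicates, and identifies
    statistically significant differential compartments with a weighted
    Mahalanobis distance under a robust (minimum covariance determinant)
    covariance estimate, chi-square p-values and covariate-weighted false
    discovery rate control. Includes differential-interaction testing on
    log2 observed/expected values of significant interactions, a synthetic
    Hi-C generator with planted compartment structure for validation, and a
    file-based pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    Matrix,
    limma,
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
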
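Package: retdeconv
Title: Calibration-Based Detection of Cell-Type-Specific Differential
    Expression in Bulk RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting bulk RNA-seq differential expression into
    cell-type composition change and within-cell-type expression change.
    Selects cell-type-specific marker genes from a labeled single-cell
    reference (Wilcoxon rank-sum testing with expressed-fraction gates),
    estimates per-sample cell-type proportions by non-negative least squares
    against a single-cell signature matrix, estimates per-cell-type
    proportion change between conditions as the geometric mean of bulk
    marker-gene fold changes, and calibrates bulk expression by that
    proportion change before negative-binomial Wald testing, yielding
    cell-type-specific differentially expressed genes. Includes a
    negative-binomial mixture simulator with full ground truth for
    validating every stage, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
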
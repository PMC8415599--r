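Package: mixqc
Title: Data-Driven Quality Control for Single-Cell RNA-Seq via Mixtures of Regressions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Flags compromised cells in single-cell RNA-seq data by jointly
    modeling the percent of counts mapping to mitochondrial genes and library
    complexity (number of detected genes) as a two-component mixture of linear
    regressions fitted by expectation-maximization. Cells are removed by their
    posterior probability of belonging to the compromised-cell component, with
    optional boundary corrections (keeping all cells below the intact-component
    line, and enforcing a left cutoff for cells dominated in both metrics).
    Includes uniform percent-mitochondrial and median-absolute-deviation
    baseline filters for comparison, a synthetic-data generator with the
    two-regime structure the model assumes, readers and writers for 10x-style
    MatrixMarket directories and per-cell metrics tables, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    splines,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
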
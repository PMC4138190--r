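Package: wgametrics
Title: Quality Metrics for Single-Cell Whole-Genome Amplification
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative metrics for benchmarking single-cell
    whole-genome amplification (WGA) chemistries from sequencing data:
    read-pair specificity classification, binned mapping densities with
    Lorenz-curve/Gini uniformity analysis and power-spectrum roll-off
    estimation, a sliding-window copy-number resolvability statistic,
    gain-dependent amplification-error modelling with per-cycle error
    rates, duplex molecular-barcode consensus calling, and LG50 assembly
    contiguity with a failure sentinel.  A seeded simulator of
    WGA-biased sequencing (Lorentzian bias fields, gain-dependent
    errors, read-pair geometry, contamination, barcoded read families)
    makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    Biostrings,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
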
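Package: allochrony
Title: Temporal Reproductive Isolation and Mating-Time Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies daily temporal (allochronic) reproductive isolation
    between two moth pheromone strains from timed mating trials, using the
    Hardy-Weinberg expected-offspring statistic on hourly mating-time windows,
    with stratified bootstrap confidence intervals and multiplicative
    combination of sequential reproductive barriers. Also provides a
    companion bulk RNA-seq time-course stage: counts-per-million
    normalisation, weak-expression filtering, a nine-contrast log2
    fold-change design with Benjamini-Hochberg correction, strain-by-timepoint
    mean expression profiles, and pairwise profile correlations. A
    synthetic-data module simulates both mating trials and negative-binomial
    count matrices with known ground truth so every stage is testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
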
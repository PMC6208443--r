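Package: hetkit
Title: Heterochromatin Methylation and Binding Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for downstream analysis of plant heterochromatin data:
    binwise differentially methylated region (DMR) calling from per-cytosine
    bisulfite counts via Fisher's exact test with Benjamini-Hochberg FDR
    control, region-set overlap and annotation analytics with length-matched
    shuffled null models, ChIP coverage-track arithmetic and scale-region
    metaplots, and simulation plus nonlinear least-squares fitting of
    isothermal titration calorimetry (ITC) binding isotherms. Includes a
    seeded synthetic-data generator (toy genome, transposable-element
    annotation, two-genotype methylomes, ChIP tracks and peaks, noisy
    isotherms) so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
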
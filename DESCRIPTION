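Package: readthrough
Title: Stop Codon Readthrough Discovery from Motif Census to Reporter
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and quantifying stop codon readthrough
    in mRNAs. Provides a genome-wide census of stop-codon contexts with a
    binomial depletion/enrichment test against a position-frequency null,
    extraction and translation of readthrough extension open reading
    frames with dual-luciferase reporter-insert design, a phylogenetic
    coding-potential score for reference-framed codon alignments
    (coding-versus-noncoding likelihood ratio computed by Felsenstein
    pruning) with per-species frame-integrity event calling, and
    quantification of dual-luciferase readthrough efficiencies,
    transactivation fold-changes and dose-response shifts. Synthetic-data
    generators with known ground truth make every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    Matrix,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
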
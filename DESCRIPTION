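Package: primarch
Title: Degenerate 16S rRNA Primer Design and In-Silico Evaluation for Archaea
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for designing and evaluating degenerate PCR primers
    targeting archaeal 16S rRNA genes. Scans taxonomically annotated
    reference alignments for conserved stretches, constructs degenerate
    primers under a nine-point acceptance scheme (coverage, 3'-terminal
    specificity, rare-phylum inclusivity, physicochemical bounds),
    simulates PCR for primer pairs with per-taxon coverage and specificity
    tables, and classifies query OTUs as novel taxa from best-hit global
    alignment identities against a reference set. Includes a deterministic
    synthetic-data generator with planted ground truth for end-to-end
    validation without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    Biostrings,
    jsonlite,
    yaml,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
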
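Package: circkit
Title: Consensus Calling, Conservation Scoring and Functional Annotation of Circular RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building a multi-species circular RNA (circRNA) atlas from
    back-splice junction (BSJ) call tables: consensus circRNA calling across multiple
    detection tools, FPM quantification, host-gene assignment and subclass
    classification (exonic, intronic, 5'-UTR, 3'-UTR, antisense, intergenic, plus a
    non-repeat flag), cross-species ortholog detection via reciprocal best hits on
    BSJ flanking sequences, a Multiple Conservation Score (MCS) combining species-,
    tissue- and individual-level conservation, and an integrated
    circRNA-mRNA-miRNA-RBP annotation network with GO/KEGG function propagation.
    Includes a deterministic synthetic-fixture generator with planted ground truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    data.table,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
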
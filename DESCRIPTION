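Package: neonull
Title: Nullomer-Based Detection of Known Neoepitopes and Gene Fusions in
    Cell-Free RNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds databases of nullomers (k-mers absent from the human
    consensus coding sequences) that tag known neoepitope-producing point
    mutations and gene-fusion junctions, and detects those nullomers in
    stranded paired-end RNA-seq reads such as plasma cell-free RNA.
    Candidate reads are filtered with an alignment-score threshold that is
    linear in aligned length (the minimum expected score), soft-clip and
    mapping-quality rules, and junction-flank requirements; per-target read
    coverage is aggregated into annotated neoepitope and fusion reports.
    Includes retention filters for externally produced HLA-binding and
    germline-frequency tables, cohort-level normalization and
    generic/discriminative categorization, and a deterministic synthetic
    reference and read simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
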
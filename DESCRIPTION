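Package: directvc
Title: Reference-Free Variant Calling by Direct Read Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genetic variants without mapping reads to a reference
    genome, by direct lexicographic comparison of read suffixes between a
    normal and a mutated sequencing sample. Reads are stored 2-bit packed in
    blocks, suffixes are partitioned by k-mer prefix and sorted, breakpoint
    clusters (shared d-mer anchor, divergent next column) are filtered by
    read-support and variant-fraction cutoffs, and per-cluster consensus
    sequences are typed as SNV, insertion, deletion, inversion or complex.
    Includes a paired-end read simulator with variant implantation and an
    evaluator computing sensitivity, positive predictive value and F-measure
    against a truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
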
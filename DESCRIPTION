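Package: tdrkit
Title: Mapping, Naming and Quantification of tRNA-Derived RNAs from Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns adapter-trimmed small RNA sequencing reads to mature and
    pre-tRNA reference libraries under a hierarchical error-type scheme
    (exact, mismatch and deletion stages that proxy reverse-transcriptase
    errors caused by tRNA chemical modifications), builds per-family
    positional coverage profiles, names the dominant tRNA-derived RNA (tDR)
    of each tRNA family with a positional grammar (tRNA-half / tRNA-fragment
    classes and 5'/3'/loop/leader/trailer/body location suffixes), quantifies
    relative abundance with full multi-mapping counts, and renders per-sample
    coverage maps. Includes a reference-library builder for gtRNAdb-style
    tRNA gene tables and a synthetic reference/read simulator with truth
    tables for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
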
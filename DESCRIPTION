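Package: circvariants
Title: Cataloging and Translation Analysis of Circular RNA Splice Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for downstream analysis of circular RNA (circRNA)
    annotations produced by backsplice-junction callers such as
    CIRCexplorer2. Groups circRNA isoforms into splice-variant families
    sharing a backsplice junction, reconstructs mature circular
    sequences from a genome and exon blocks, enumerates open reading
    frames on circular topology (junction-spanning, nested and
    stop-free "infinite" ORFs translated by rolling-circle translation),
    annotates wrap-aware DRACH/m6A and RNA-binding-protein motif sites,
    predicts divergent-primer and rolling-circle-amplification product
    sizes, and provides delta-Ct arithmetic for polysome-fraction and
    immunoprecipitation RT-qPCR readouts. Includes a synthetic-data
    generator with a ground-truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
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
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
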
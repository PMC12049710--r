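Package: seqcoasm
Title: Sequential Co-Assembly of Multi-Sample Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for sequential metagenome co-assembly: assemble a
    subset of samples, subtract reads that map concordantly to that initial assembly
    from every sample, then co-assemble the subset reads together with the remaining
    unaligned reads. Bundles a deterministic single-k de Bruijn unitig assembler, a
    seed-and-extend paired-end mapper with concordant/discordant classification, a
    multi-sample community read simulator with per-read ground truth, depth-planning
    arithmetic, and a reference-based plus reference-free assembly evaluation suite
    (genome fraction, duplication ratio, misassembly counts, mismatch rate, auN/N50,
    overall read alignment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    tools,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
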
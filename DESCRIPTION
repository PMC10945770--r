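Package: evoextent
Title: Extent of Molecular Evolution from Gene Trees and Root-to-Tip Trait
    Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the extent of molecular evolution of genes from
    phylogenetic trees (total tree length, root-to-tip and patristic
    distances, percentile ranks against orthogroup cohorts, stratified
    bootstrap over multi-copy gene families) and tests for directional
    selection on continuous traits by regressing trait values on
    root-to-tip distance, with ancestral-trait inference from the
    regression intercept and conversion of slopes into per-substitution
    and per-million-year rates of change. Includes codon-alignment
    threading and trimming utilities and a synthetic-data generator for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
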
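Package: panortho
Title: Gene-Based Pangenome Classification, Duplication and Selection Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for gene-based super-pangenome analysis across many
    annotated genomes: orthogroup occupancy and pan-gene set classification
    (core, softcore, dispensable, private), rarefaction and pangenome openness
    modelling, taxon-group presence/absence variation, Fisher exact term
    enrichment, collinearity-based classification of whole-genome versus tandem
    duplicates, Nei-Gojobori Ka/Ks estimation, a Goldman-Yang codon-model
    likelihood engine with branch and branch-site likelihood-ratio tests for
    rapidly evolving and positively selected genes, single-copy supermatrix
    phylogeny utilities, and a leucine-rich-repeat receptor-like kinase domain
    cascade. Includes synthetic-data generators that emulate the statistical
    structure of multi-genome orthogroup data so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
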
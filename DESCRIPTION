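Package: gbsdiv
Title: Diversity and Differentiation Analysis of Genotyping-by-Sequencing SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing genetic diversity in crop germplasm
    collections genotyped with biallelic SNP panels (GBS/DArTseq-style data).
    Implements read- and marker-level quality filtering, Nei's gene diversity
    and polymorphic information content, partitioning of diversity into
    within- and between-population components (Ht, Hs, Gst) with an
    island-model gene-flow estimate, neighbor-joining dendrograms with
    bootstrap support, allele-specific gene-marker frequency profiling with
    band-size novelty flagging, and reference-anchored characterization of
    insertion/deletion alleles from pairwise sequence alignment. A synthetic
    data module simulates structured multi-group panels under the
    Balding-Nichols model, gene-marker call tables, indel-bearing sequence
    pairs and FASTQ reads so that every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
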
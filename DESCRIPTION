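Package: hgtmosaic
Title: Detection of Horizontal Gene Transfer Footprints in Parasitic Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to detect horizontal gene transfer (HGT) in parasitic
    plant genomes from standard comparative-genomics outputs.  Implements a
    taxon-aware interval-tiling algorithm that assigns mitochondrial contig
    positions to donor lineages from multi-database BLAST hits, foreign-region
    calling with cross-species conservation screening, a sequential open
    reading frame filtering cascade and candidate-orthogroup selection for
    nuclear HGT, a gene-tree topology classifier applying monophyly,
    sister-clade and bootstrap-support rules, and Fisher-exact term
    overrepresentation with Benjamini-Hochberg correction.  A synthetic-data
    generator plants foreign tracts in mosaic contigs and emits labelled
    gene-tree scenarios with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    IRanges,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
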
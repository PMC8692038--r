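Package: silkforge
Title: Targeted Reconstruction and Characterisation of Spider Silk Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for curating spidroin (spider silk protein) gene
    catalogues from sequencing reads. Implements terminal-domain-seeded,
    position-weight-matrix based extension of highly repetitive silk genes
    from short reads with long-read full-length confirmation, repeat-motif
    cataloguing and family classification, N-terminal-domain neighbor-joining
    phylogenies with bootstrap support, transcripts-per-million expression
    and proteome composition profiling, and silk fibre property summaries
    (tensile mechanics and wide-angle X-ray scattering crystallinity). A
    synthetic-data module generates spidroin gene models and Illumina-like /
    Nanopore-like reads so the whole pipeline is exercisable without any
    external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
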
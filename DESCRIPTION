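Package: editomescan
Title: RNA Editome Detection and Characterization from Matched DNA and RNA Variant Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes RNA editing sites from matched DNA and
    RNA variant calls of the same individual. Implements a multi-caller merge
    (union for DNA, intersection for RNA), RNA-DNA difference identification
    with genotype-consistency removal, four pileup-evidence filters (base
    quality, depth, read-end distance, supporting reads), and germline
    subtraction against known SNP tables. Surviving sites are annotated
    against gene models and repeat tracks, classified into seven cross-stage
    presence patterns over a four-sample tumor progression design, and
    analysed for functional impact: hypergeometric enrichment of 3'UTR sites
    in microRNA target regions, synonymous/non-synonymous recoding in coding
    sequence, and Kolmogorov-Smirnov comparison of expression changes of
    edited transcripts against background. A self-consistent synthetic-data
    generator with known ground truth drives validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
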
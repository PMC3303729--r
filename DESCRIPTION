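Package: orthoexon
Title: Exon-Level Orthology Assignment Between Annotated Gene Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns orthology between individual exons of pre-paired
    orthologous genes from two species. Overlapping isoform exon variants
    are merged into united exons; a two-step homology search (nucleotide
    local alignment, then translated frame-pair fallback) produces
    exon-vs-exon hits within each gene pair; best-reciprocal-hit detection,
    collapse of multi-hits within one united exon, fused/split (intron
    gain/loss) event detection and order-constrained anchor mapping turn
    hits into final one-to-one and one-to-many exon assignments. Includes
    downstream summaries (gene-region distribution, exon length
    conservation, reading-frame mod-3 analysis) and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
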
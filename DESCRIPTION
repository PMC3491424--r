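Package: epifacet
Title: Faceted Text-Index Search and Enrichment Analytics for Genomic
    Region Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates genomic region sets (BED intervals) against
    genome and epigenome tracks, encodes each region as a document of
    hierarchical keywords (overlap flags, zero-padded numeric bins,
    gene links), and builds a prefix-searchable word index supporting
    AND, OR, prefix-completion, lexicographic range and gene-document
    JOIN queries.  On top of the query engine it provides interactive
    analytics: overlap bar summaries, histograms and coarse partitions
    of numeric attributes, genomic neighborhood profiles, bubble-chart
    data, gene-term enrichment against randomized control sets, and
    serializable filter chains for reproducible iterative refinement.
    A deterministic synthetic fixture generator with a planted-truth
    ledger makes the whole system testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
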
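Package: ithscape
Title: Multi-Sector Intratumoural Heterogeneity Analysis of Immune,
    Transcriptomic and Genomic Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intratumoural heterogeneity (ITH) from multi-sector
    tumour profiling and links it to immune escape and outcome. Computes
    immune-, RNA-, DNA- and density-based ITH scores with median-split
    grouping; builds neighbour-joining phylogenies of tumour sectors from
    Hamming and rank-correlation distances; calls neoantigen clonality,
    immunoediting (observed over expected neoantigenic mutations from the
    empirical trinucleotide spectrum), HLA loss of heterozygosity and
    altered genome fraction; infers bipartite transcriptome-immune
    correlation networks from differentially expressed genes; and
    segregates patients by an ITH-associated expression signature for
    Kaplan-Meier, log-rank and Cox survival analysis with bootstrap FDR
    and leave-one-out stability. Includes a fully parameterised synthetic
    multi-sector cohort generator with ground truth for end-to-end
    validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
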
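Package: mirflow
Title: Small RNA-Seq miRNA Profiling and Two-Library Differential Expression
Version: 0.1.0
Authors@R:
    person("mirflow", "maintainers", email = "mirflow@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for microRNA profiling from small
    RNA sequencing of two conditions without replicates: adapter trimming,
    length and low-complexity ("junk") filtering, collapsing to counted
    unique tags, contaminant classification against reference sets
    (rRNA/tRNA/snRNA/snoRNA/other ncRNA/mRNA/repeats), known miRNA
    identification with isomiR variant naming, novel miRNA candidate
    evaluation from genomic hairpin loci, per-million normalization with an
    exact two-library count test (Audic-Claverie conditional distribution)
    and fold-change classification, hypergeometric GO/pathway term
    enrichment of seed-match predicted targets, bipartite miRNA-gene
    network construction, and 2^-ddCt qPCR validation. Includes a seeded
    synthetic-data generator producing reference bundles and FASTQ
    libraries with known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    S4Vectors,
    digest,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
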
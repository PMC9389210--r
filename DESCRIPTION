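Package: cosagr
Title: Strain-Resolved Single-Cell Genomics: Composite SAG Construction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building composite single-amplified genomes (CoSAGs)
    from bacterial single-cell sequencing data. Quality-controls
    MDA-amplified single-cell reads, estimates genome completeness and
    contamination from single-copy marker genes with MIMAG-style quality
    tiers, computes three pairwise genome-similarity measures
    (fragment-based two-way average nucleotide identity, canonical
    tetranucleotide-frequency correlation, single-copy marker homology),
    clusters SAGs of the same host into same-strain groups, cleans pooled
    reads by iterative cross-reference mapping with chimera splitting, and
    emits co-assembly-ready read pools. Includes a ground-truthed synthetic
    SAG generator emulating strain divergence, MDA coverage bias, locus
    dropout, chimeric reads and contamination, so every stage is testable
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
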
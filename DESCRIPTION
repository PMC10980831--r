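Package: regionbench
Title: Benchmarking the Taxonomic Resolution of 16S rRNA Variable Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks 16S rRNA gene variable regions by how faithfully their
    phylogenies reproduce whole-genome relationships within a bacterial
    genus. Provides in-silico PCR extraction of amplicons from degenerate
    primer pairs, per-column Shannon-entropy profiling of alignments,
    fragment-based average nucleotide identity (ANI) with 95%-threshold
    grouping and dereplication, distance-based tree reconstruction
    (neighbor joining, UPGMA, bootstrap support), generalized
    Jaccard-Robinson-Foulds and mutual-clustering-information tree
    comparison, oligonucleotide-frequency ordination, and a benchmark
    orchestrator producing per-genus region rankings and z-score tables.
    A synthetic-genus generator with a known species tree, planted
    mutational hot regions and controllable ANI-group structure makes
    every stage testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
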
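Package: seasnp
Title: Seasonal SNP Enrichment in Gut Metagenomes with a Simulation-Based
    Caller Benchmark
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for strain-level single-nucleotide-polymorphism (SNP)
    analysis of seasonal gut-metagenome cohorts, together with a fully
    synthetic benchmark for pileup-based SNP callers. The benchmark layer
    synthesizes reference genomes, plants a ground-truth SNP list, simulates
    error-bearing 75 bp paired-end reads, calls SNPs from true-origin pileups
    with threshold semantics, and scores calls by sensitivity, selectivity
    and SNP coverage. The seasonal layer generates a synthetic three-season
    cohort with planted wet-season SNP enrichment and season-associated
    strain backgrounds, computes per-species and per-gene SNP densities,
    selects cyclic seasonal patterns with a self-implemented Wilcoxon
    rank-sum test, clusters allele-frequency-thresholded SNP profiles with
    Manhattan distances, and scores season concordance of the resulting
    trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
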
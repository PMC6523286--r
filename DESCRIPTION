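Package: shadowY
Title: Detection of Cryptically Y-Linked SNP Array Markers and Y Retrocopy
    Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects SNP-array markers that are cryptically Y-linked
    ("shadow-Y" markers): array probes mapped to autosomes or the X
    chromosome whose apparent heterozygosity in males is cross-hybridization
    of a diverged, hemizygous Y-chromosome paralog. Provides a sex
    case-control scan with an exact dominant-model test and Bonferroni
    significance calling, genotype-pattern classification and region
    clustering of hits, a male-versus-female alignment-feature contrast that
    operationalizes the duplication signature of Y retrocopies, global
    pairwise alignment and shared-polymorphism analysis of retrocopy
    sequences, Dollo parsimony placement of retrocopy gain events on a
    species tree, and seeded simulators for every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    seqinr,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    Biostrings,
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
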
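Package: xintro
Title: X-Linked Contig Detection and Bayesian Genomic Cline Analysis of
    Hybrid Zone Introgression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-stage population-genomic inference in species with
    fragmented genome assemblies. Stage one identifies X-linked assembly contigs
    from male/female mapped-read-count ratios (exact conditional count tests on
    CPM-filtered contigs) and validates them by homology to an annotated
    reference karyotype and by qPCR relative quantification. Stage two tests
    whether X-linked SNPs show reduced and directionally biased introgression
    across a hybrid zone, using per-locus Bayesian genomic clines (direction
    alpha and rate beta, estimated jointly with per-individual hybrid indices by
    MCMC, with an optional genotype-uncertainty likelihood over allele-specific
    read counts) and a permutation comparison of X-linked against autosomal SNP
    sets. Simulators for every input format make the full pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
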
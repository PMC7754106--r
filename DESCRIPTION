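Package: locusrank
Title: Partition GWAS Risk Loci and Rank Candidate Genes by Weighted Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions genome-wide association study (GWAS) summary
    statistics into risk loci by iterative lead-variant extraction with
    window merging, computes pairwise linkage disequilibrium (D, D-prime,
    r-squared) from an unphased diploid reference panel by EM
    haplotype-frequency estimation, assembles per-gene evidence from
    expression, eQTL colocalization, literature, constraint, rare-variant
    burden and disease-gene inputs, and ranks candidate genes at each
    locus by a user-weighted conclusion score. Ships a seeded synthetic
    data generator with planted causal variants and haplotype-block LD so
    the whole pipeline is testable without external downloads, plus a
    small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    S4Vectors,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
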
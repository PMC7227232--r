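Package: sweepscan
Title: Multi-Statistic Genome Scans for Signatures of Selection in
    Multi-Breed SNP Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects signatures of selection in dense SNP genotype data from
    multiple populations. Computes five per-breed selection statistics
    (haplotype homozygosity H1 and H12 over fixed-SNP windows, Tajima's D,
    one-vs-rest Weir-Cockerham FST, per-site nucleotide diversity) and
    combines them into the de-correlated composite of multiple signals (DCMS)
    with rank-based one-tailed p-values, a robust (minimum covariance
    determinant) correlation model, a robust-normal fit and Storey q-values.
    Also implements the single-SNP FLK test of allele-frequency
    differentiation against a drift tree, with Reynolds distances,
    neighbour-joining, midpoint rooting and a tree-derived kinship matrix,
    and can post-process externally computed hapFLK statistic tracks.
    Selection regions are called from q-value tracks with a seed/boundary
    rule, and candidate genes around each region peak are identified and
    distance-ranked. A Balding-Nichols synthetic-data generator with
    tree-structured drift, injected hard sweeps and missingness supports
    calibration and recovery testing without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    ape,
    phangorn,
    vcfR,
    jsonlite,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
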
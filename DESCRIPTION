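Package: sweepscan
Title: Selective-Sweep Scans from Multi-Sample SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of selective sweeps in diverged populations from
    multi-sample SNP genotype panels. Implements hard site filtering of
    variant calls (QD/MQ/FS/QUAL, call rate, minor allele frequency),
    per-population site statistics (transition/transversion ratio, fixed
    non-reference sites, shared and private segregating sites, windowed
    nucleotide diversity), a pooled-heterozygosity (ZHp) sliding-window
    scan, a from-scratch cross-population extended haplotype homozygosity
    (XP-EHH) scan with SNP-density-binned empirical p-values, and candidate
    region and gene calling. A forward-in-time two-population simulator
    with haplotype-copy sweep injection provides fully synthetic,
    truth-annotated fixtures so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
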
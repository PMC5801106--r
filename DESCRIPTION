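Package: sweepscreen
Title: Selective-Sweep and Staged Expression Screening for Two-Group
    Resequencing Panels
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Candidate-gene screening for a panel of accessions split into
    two phenotype groups (e.g. high-anthocyanin versus non-anthocyanin
    rice). One arm scans resequencing SNPs for selective sweeps: bi-allelic
    and Hardy-Weinberg/MAF quality control, windowed nucleotide diversity
    per group, the reduction-of-diversity (ROD) statistic, pooled
    heterozygosity (Hp) with its genome-wide Z transform (ZHp), a Hudson
    FST track, threshold-based sweep-region calling and gene overlap
    reports. The other arm screens per-accession FPKM tables for staged
    twofold expression changes across time points with term-set enrichment
    (one-sided Fisher tests and permutation FDR). A synthetic-data
    generator plants sweeps and differentially expressed genes so the full
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
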
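Package: asocmap
Title: Allele-Specific Open Chromatin Mapping from Heterozygous SNP Read Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps allele-specific open chromatin (ASoC) from ATAC-seq allelic
    read counts at heterozygous SNPs. Applies SNP qualification filters
    (biallelic heterozygous genotype, read depth, per-allele count, dbSNP
    membership, chromosome exclusion), tests allelic imbalance with an exact
    two-sided binomial test against a null allelic fraction of 0.5, controls
    the false discovery rate with Benjamini-Hochberg step-up correction, and
    calls ASoC SNPs at a chosen FDR threshold. Downstream steps restrict SNPs
    to open-chromatin peaks cleaned of blacklisted regions, annotate
    promoter-proximal versus distal SNPs by TSS distance, co-localize ASoC
    SNPs with GWAS risk loci through linkage-disequilibrium proxies, assign
    candidate target genes through activity-by-contact (ABC) enhancer-gene
    links, and compute simple Fisher or permutation set enrichment. A
    beta-binomial synthetic-data generator with planted ground truth supports
    calibration, power, and end-to-end recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomeInfoDb,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
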
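#!/usr/bin/env Rscript
# Qualify SNPs and call ASoC: depth >= 20, both alleles >= 2 reads,
# heterozygous, autosomal, dbSNP-annotated; exact two-sided binomial test
# against allelic fraction 0.5; BH correction across all qualified SNPs;
# calls at FDR < 0.05. Also runs the reference-bias QC.

suppressMessages(library(asocmap))

counts <- read_counts("results/sim/counts.tsv")
truth <- read.table("results/sim/truth.tsv", header = TRUE, sep = "\t")

filt <- apply_qualification_filters(counts)
print(filt$report)
writeLines(filter_report_json(filt$report), "results/filter_report.json")

res <- call_asoc(filt$counts, fdr_threshold = 0.05)
write_asoc_results(res, "results/asoc_results.tsv",
                   bed_path = "results/asoc_snps.bed")

n_called <- sum(res$is_asoc)
tr <- truth[match(res$snp_id, truth$snp_id), ]
tp <- sum(res$is_asoc & tr$is_asoc)
cat(sprintf("ASoC SNPs called at FDR < 0.05: %d of %d qualified\n",
            n_called, nrow(res)))
cat(sprintf("  planted ASoC recovered: %d / %d (sensitivity %.3f)\n",
            tp, sum(tr$is_asoc), tp / sum(tr$is_asoc)))
cat(sprintf("  false discoveries among calls: %d (FDP %.4f)\n",
            n_called - tp, (n_called - tp) / max(n_called, 1)))

qc <- reference_bias_qc(res)
print(qc)
write.table(qc$volcano, "results/volcano.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Results written to results/asoc_results.tsv, results/volcano.tsv\n")
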
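# asocmap

Mapping **allele-specific open chromatin (ASoC)** from ATAC-seq allelic read
counts at heterozygous SNPs, and placing the calls in genomic and GWAS
context.

At a heterozygous SNP inside an open-chromatin region, reads covering the
site carry one of the two alleles. If the variant does not affect
accessibility, reads split evenly between alleles; a variant that alters
chromatin accessibility in *cis* skews the split. `asocmap` turns this into
a genome-wide screen:

1. **Qualification** — keep biallelic heterozygous SNPs (`GT` 0/1) with
   total allelic depth DP ≥ 20, both alleles supported by ≥ 2 reads, present
   in dbSNP, outside chrX/Y/MT and decoy contigs.
2. **Testing** — for each SNP with reference/alternative counts (x, n−x),
   the exact two-sided binomial test of H₀: θ = 0.5,
   p = P(X ≤ k) + P(X ≥ n−k) with k = min(x, n−x) under Binomial(n, ½)
   (no normal approximation). Benjamini–Hochberg step-up correction is
   applied across all qualified SNPs; a SNP is called ASoC when q < 0.05.
3. **Context** — peaks overlapping blacklisted regions are dropped whole,
   calls are restricted to the remaining open chromatin, and each SNP is
   binned by distance to the nearest TSS (promoter-proximal ≤ 5 kb,
   distal > 50 kb).
4. **GWAS integration** — GWAS index SNPs are expanded to their LD proxies
   (r² ≥ 0.8), a risk locus is "hit" when a proxy is an ASoC SNP, and hit
   SNPs falling inside activity-by-contact (ABC) enhancers are assigned the
   linked target gene. A simple Fisher/permutation set-enrichment utility is
   included for annotation overlaps.
5. **Synthetic data** — a seeded beta-binomial generator plants ground-truth
   ASoC SNPs, peaks, blacklist intervals, TSS records, GWAS loci with LD
   proxies, and ABC links, so calibration (FDR), power, and end-to-end
   recovery are all measurable against known truth.

The intended user analyses bulk ATAC-seq of iPSC-derived neural and glial
cell types (microglia, astrocytes, neurons) but nothing is cell-type
specific: any table of per-SNP allelic counts works.

## Worked example

The `analysis/` directory is a numbered workflow over a synthetic study of
20,000 heterozygous SNPs (10% planted ASoC with alternative-allele fraction
0.25 or 0.75, depth 20 + Poisson(40)):

```sh
Rscript analysis/01_simulate_study.R   # counts, peaks, TSS, GWAS/LD, ABC
Rscript analysis/02_call_asoc.R        # filters, binomial test, BH, QC
Rscript analysis/03_genomic_context.R  # blacklist cleaning, peaks, TSS bins
Rscript analysis/04_gwas_integration.R # LD proxies, colocalization, ABC
Rscript analysis/05_calibration.R      # FDR calibration and power grid
```

Step 02 prints:

```
ASoC SNPs called at FDR < 0.05: 1781 of 20000 qualified
  planted ASoC recovered: 1723 / 2043 (sensitivity 0.843)
  false discoveries among calls: 58 (FDP 0.0326)
Reference-bias QC over 20000 SNPs
  pooled mean allelic ratio: 0.4996 (SE 0.000728)
  bias flag (|mean - 0.5| > 0.02): ok
```

i.e. the BH-thresholded binomial test keeps the realized false-discovery
proportion (0.033) under the nominal 0.05 while recovering 84% of planted
effects at this depth, and the pooled reference-allele ratio sits on 0.5, so
no reference-mapping bias is flagged. Step 04 then reports:

```
GWAS colocalization: 3 of 10 loci with >= 1 ASoC SNP (30.0%)
  planted ASoC-proxy loci recovered: 3 / 3
ABC target genes assigned to 3 colocalized risk SNPs
```

— exactly the three loci whose LD proxies were planted on ASoC SNPs, each
assigned its planted ABC target gene.

The same functions are available interactively:

```r
library(asocmap)
cfg <- sim_config(n_snps = 5000, pi_asoc = 0.1, theta_asoc = 0.75, seed = 11)
sim <- simulate_allelic_counts(cfg)
res <- call_asoc(apply_qualification_filters(sim$counts)$counts)
table(res$is_asoc)
```

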
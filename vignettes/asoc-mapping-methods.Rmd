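---
title: "Methods: allele-specific open chromatin mapping in asocmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific open chromatin mapping in asocmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asocmap)
```

## The statistical model

At a heterozygous SNP covered by `n = ref_count + alt_count` ATAC-seq reads,
the number of alternative-allele reads under the null of no allelic effect
on accessibility is `X ~ Binomial(n, 0.5)`: each read samples one of the two
chromosomes at random. `asocmap` tests this null with the exact two-sided
tail sum

p = P(X ≤ k) + P(X ≥ n − k),  k = min(ref, alt),

clamped at 1. Because the Binomial(n, ½) pmf is symmetric, this tail-doubling
definition coincides with the "sum of all outcomes no more likely than the
observed one" convention implemented by `binom.test()`; the test suite
asserts that equality exhaustively for n ≤ 60, which removes any dependence
on a particular package's tie handling. Tail sums use `pbinom()`, i.e. exact
summation, never a normal approximation, and p-values are kept in full double
precision (the smallest attainable value at depth n is `2 * 0.5^n`, never
rounded to 0) so that −log transforms downstream remain finite.

Benjamini–Hochberg step-up adjustment is then computed across **all
qualified SNPs of one analysis set** (one cell type at a time — never pooled
across cell types, since per-cell-type ASoC counts are the quantity of
interest), and a SNP is called ASoC when `q < 0.05`. The strict inequality
is a deliberate, conservative reading of an "FDR = 0.05 threshold" whose
boundary behaviour is otherwise unspecified; it matters only for SNPs whose
q-value lands exactly on the threshold.

### Qualification filters

Filters precede testing, in a fixed order that also defines the rejection
accounting (each SNP is charged to the first rule it fails): genotype
(heterozygous `0/1` or `0|1`) → chromosome (chrX/Y/MT and decoy/patch
contigs, both `"chr1"` and `"1"` dialects accepted) → dbSNP membership
(an input flag, not a live lookup, so the dbSNP version is pinned by the
caller) → depth `DP ≥ 20` → per-allele count `≥ 2`. `DP` is defined as
`ref_count + alt_count`, i.e. exactly the `n` the binomial test uses; reads
carrying third alleles are outside both the filter and the test. This is a
configuration point worth knowing about: an aligner's own DP can include
such reads and differ slightly.

### Reference-bias QC

Aligners map reference-allele reads slightly more readily than
alternative-allele reads unless the upstream pipeline corrects for it.
`reference_bias_qc()` summarizes the pooled mean reference-allele ratio, its
standard error, and the count-weighted ratio, and flags the set when the
pooled mean deviates from 0.5 by more than a margin (default 0.02 — roughly
the shift produced by a 10% multiplicative capture bias, far above sampling
noise at any realistic SNP count). The accompanying volcano table (allelic
ratio vs −log₂ p) is the visual check: an unbiased experiment is symmetric
about 0.5. The flag assumes planted or real ASoC effects are
direction-symmetric; a strongly one-directional effect set shifts the pooled
mean and is flagged, which is the correct behaviour for a QC whose job is to
detect asymmetry.

## Genomic context

Peaks live in BED convention (0-based, half-open) at every interface; SNP
positions are 1-based. A SNP at position p is inside peak [s, e) iff
`s ≤ p − 1 < e`; the boundary cases (p = s excluded at the left edge in
1-based terms, p = e included) are pinned by an exhaustive position sweep in
the tests. Peaks overlapping a blacklist interval by ≥ 1 bp are dropped
whole, never trimmed — trimming would change peak identity and silently move
SNPs across the in/out boundary. TSS distance is the strand-agnostic point
distance to the nearest TSS on the same chromosome; the promoter-proximal
bin is `distance ≤ 5000` (reading "within 5 kb" as inclusive) and the distal
bin is `distance > 50000`, both configurable. Interval queries run on
GenomicRanges; their correctness is cross-checked against O(n·m) brute-force
oracles rather than trusted.

## GWAS integration

Risk loci are taken as given rows of an index-SNP table — no window
heuristic invents locus boundaries — and the proxy set of a locus is the
index SNP plus every SNP with `r² ≥ 0.8` against it in the supplied LD
table (inclusive threshold; table symmetrized on load). A locus is *hit*
when any proxy is a called ASoC SNP; a SNP proxying several loci counts for
each of them, undeduplicated, because the per-locus interpretation is the
unit of interest. ABC target assignment is a point-in-interval join of SNP
positions against enhancer intervals, one output row per (SNP, linked gene).

`set_enrichment()` is plain 2×2 set-overlap arithmetic
(fold = (|A∩B|/|A|)/(|B|/|U|), one-sided Fisher or seeded permutation p).
It is deliberately transparent plumbing for annotation overlaps; it is not a
hierarchical GWAS-enrichment model, and its folds are not comparable to
enrichment estimates from such models.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, with
planted truth so that error rates are measurable:

* **Depth**: `20 + Poisson(40)` per SNP by default. The shift guarantees
  every simulated SNP clears the DP ≥ 20 filter, which decouples filter
  tests from power tests; lowering the shift exercises the filter instead.
  Published deep ATAC-seq libraries do not come with a stated per-SNP depth
  distribution, so this default is a plausible stand-in, not a fit.
* **Null SNPs**: alternative-allele fraction θ = 0.5. **Planted ASoC SNPs**
  (a fraction `pi_asoc`, default 0.1): θ = `theta_asoc`, a scalar or a set
  sampled per SNP. The calibration and power experiments use the scalar
  0.75; the narrative study in `analysis/` uses the symmetric pair
  {0.25, 0.75}, since real ASoC has no preferred direction and a
  one-directional plant would (correctly) trip the bias QC.
* **Overdispersion**: counts are beta-binomial with mean θ and
  overdispersion ρ via shapes `a = θ(1−ρ)/ρ`, `b = (1−θ)(1−ρ)/ρ` — the
  standard allele-specific-expression parameterization with a single noise
  knob; ρ → 0 recovers the pure binomial, and the allelic-fraction variance
  at depth n is `θ(1−θ)(1 + (n−1)ρ)/n`. The analysis itself stays a plain
  binomial test (matching the mapping method being modelled); ρ exists to
  probe robustness, not to be estimated.
* **Reference bias**: a multiplicative capture bias b ≥ 0 maps θ to
  `θ′ = θ/(θ + (1−θ)b)` — the logit-shift form used in mapping-bias work;
  b = 1 is unbiased. The QC margin of 0.02 corresponds to b ≈ 1.08.
* **Placement**: a fraction `frac_in_peaks` of SNPs is placed uniformly
  inside simulated peaks, the rest rejection-sampled outside all peaks.
  Peaks are disjoint by construction; a stated fraction gets a planted
  blacklist interval covering its midpoint, so the expected survivor count
  is exact.
* **GWAS/LD and ABC**: r² values are *drawn* (uniform on [0.8, 1] above
  threshold, plus below-threshold decoys), not derived from haplotypes —
  the artifact needs the table structure, not population genetics. Planted
  coincidences anchor LD proxies and ABC enhancers on the most significant
  eligible planted ASoC SNPs (qualified, inside a clean peak, ranked by
  binomial p), so a correct pipeline must recover exactly the planted loci
  and links; the remaining enhancers are rejection-sampled to contain no
  simulated SNP at all.

A single integer seed drives every draw; identical (config, seed) yields
byte-identical tables, asserted in the tests by file comparison.

### What passing tests do and do not show

The generator reproduces the *count-level* structure: binomial/beta-binomial
sampling, depth variation, direction-symmetric effects, peak placement,
blacklist overlap, LD-proxy tables, enhancer links. It does not simulate
reads, alignment, read-level mapping bias, genotyping error, donor-level
repeat structure, or haplotype LD. Consequently the suite demonstrates that
the statistics and the coordinate/set logic are correct and calibrated under
the assumed model — it cannot certify robustness to upstream artefacts
(alignment bias beyond the multiplicative knob, mis-genotyped sites,
correlated SNPs within a peak), which in a real study are handled by the
upstream calibration pipeline this package consumes counts from.

## Problem sizes and numerical choices

The shipped experiments use 20,000 SNPs per study, 50 replicate studies for
FDR calibration, a 3×3 power grid (θ ∈ {0.6, 0.7, 0.8} × mean depth
∈ {40, 80, 160}) of 20,000 SNPs each, fixed depth 200 for the
parameter-recovery check (selection bias of the called subset is below 0.01
there), and 100,000 permutations for the enrichment consistency check.
These sizes put Monte-Carlo standard errors well below the effect sizes
being asserted. Ties in BH are handled by the step-up minimum (tied p-values
share a q); ties in nearest-TSS distance resolve to either side, and tests
compare distances, not indices. Degenerate inputs are contracts, not
silent results: zero-depth SNPs are rejected by `call_asoc()` (the filters
remove them), empty locus tables yield an undefined (null) hit fraction
rather than 0, and an empty universe or empty ASoC set is an error in
`set_enrichment()`.

## Known limitations

* One merged count pair per SNP per cell type; no donor-level modelling or
  haplotype-aware aggregation across neighbouring SNPs.
* The binomial test ignores overdispersion; with ρ > 0 the realized FDR
  rises above nominal (the simulator exposes exactly this).
* dbSNP membership, LD, and ABC links are consumed as given tables; their
  provenance and versions are the caller's responsibility.
* `set_enrichment()` is not a substitute for hierarchical enrichment
  models over functional annotations.
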
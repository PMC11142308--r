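# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's code paths (and GenomicRanges) so that agreement is a
# genuine dual-route check.

# Exact two-sided binomial p by direct pmf summation of both tails.
oracle_binom_p <- function(ref, alt) {
  n <- ref + alt
  k <- min(ref, alt)
  p <- sum(dbinom(0:k, n, 0.5)) + sum(dbinom((n - k):n, n, 0.5))
  min(p, 1)
}

# Two-sided p by the "sum all outcomes with pmf <= observed" convention
# (what binom.test uses); for Binomial(n, 1/2) it must equal the tail-doubling
# definition because the pmf is symmetric.
oracle_binom_p_minlik <- function(ref, alt) {
  n <- ref + alt
  d <- dbinom(0:n, n, 0.5)
  min(1, sum(d[d <= d[min(ref, alt) + 1] * (1 + 1e-7)]))
}

# Literal BH step-up from its definition: q_(i) = min_{j >= i} p_(j) * n / j.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(n),
               function(i) min(1, min(ps[i:n] * n / (i:n))), numeric(1))
  out <- numeric(n)
  out[o] <- qs
  out
}

# O(n*m) interval overlap on BED-style (0-based half-open) data.frames:
# which rows of `a` overlap any row of `b` by >= 1 bp.
oracle_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# Brute-force point-in-interval: is 1-based position pos inside half-open
# [start, end)? i.e. start <= pos - 1 < end.
oracle_point_in <- function(chrom, pos, ivs) {
  vapply(seq_along(pos), function(i) {
    any(ivs$chrom == chrom[i] & ivs$start <= pos[i] - 1 & pos[i] - 1 < ivs$end)
  }, logical(1))
}

# Exhaustive nearest-TSS distance per SNP (NA when no TSS shares the chrom).
oracle_nearest_tss <- function(snps, tss) {
  vapply(seq_len(nrow(snps)), function(i) {
    d <- abs(tss$tss_pos[tss$chrom == snps$chrom[i]] - snps$pos[i])
    if (length(d) == 0) NA_real_ else min(d)
  }, numeric(1))
}

# Random qualification-filter input for accounting-identity checks.
random_counts_table <- function(n, seed) {
  set.seed(seed)
  data.frame(
    chrom = sample(c("chr1", "2", "chrX", "Y", "chrMT", "chr1_rand_decoy"),
                   n, replace = TRUE),
    pos = sample.int(1e6, n, replace = TRUE),
    snp_id = sprintf("s%05d", seq_len(n)),
    ref = "A", alt = "G",
    ref_count = rpois(n, 15),
    alt_count = rpois(n, 15),
    genotype = sample(c("0/1", "0|1", "1/1", "0/0"), n, replace = TRUE,
                      prob = c(0.6, 0.1, 0.15, 0.15)),
    in_dbsnp = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.9, 0.1)),
    stringsAsFactors = FALSE)
}
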
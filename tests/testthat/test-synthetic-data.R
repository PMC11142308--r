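# Synthetic-data generator: determinism, null calibration, planted-effect
# recovery, overdispersion, annotation and GWAS/LD structure.

test_that("identical config and seed give byte-identical simulated output", {
  cfg <- sim_config(n_snps = 500, pi_asoc = 0.2, theta_asoc = 0.7,
                    rho = 0.02, seed = 99)
  a <- simulate_allelic_counts(cfg)
  b <- simulate_allelic_counts(cfg)
  expect_identical(a, b)
  fa <- tempfile(); fb <- tempfile()
  write_counts(a$counts, fa); write_counts(b$counts, fb)
  expect_identical(readLines(fa), readLines(fb))
  c2 <- simulate_allelic_counts(sim_config(n_snps = 500, pi_asoc = 0.2,
                                           theta_asoc = 0.7, rho = 0.02,
                                           seed = 100))
  expect_false(identical(a$counts$alt_count, c2$counts$alt_count))
})

test_that("null simulation is symmetric around allelic fraction 0.5", {
  sim <- simulate_allelic_counts(sim_config(n_snps = 100, pi_asoc = 0,
                                            rho = 0, ref_bias = 1, seed = 1))
  frac <- sim$counts$alt_count / (sim$counts$ref_count + sim$counts$alt_count)
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.5), 3 * se)
  expect_true(all(sim$counts$ref_count + sim$counts$alt_count >= 1))
  expect_true(all(sim$counts$genotype == "0/1"))
})

test_that("degenerate allelic fraction 1 at fixed depth yields (0, depth)", {
  sim <- simulate_allelic_counts(sim_config(n_snps = 1,
                                            depth_model = depth_fixed(20),
                                            pi_asoc = 1, theta_asoc = 1.0,
                                            rho = 0, seed = 5))
  expect_identical(sim$counts$ref_count, 0L)
  expect_identical(sim$counts$alt_count, 20L)
})

test_that("planted ASoC fraction and allelic fraction match the sample-mean oracle", {
  cfg <- sim_config(n_snps = 50000, pi_asoc = 0.1, theta_asoc = 0.75,
                    depth_model = depth_shifted_poisson(20, 40), rho = 0.01,
                    seed = 7)
  sim <- simulate_allelic_counts(cfg)
  expect_identical(nrow(sim$truth), 50000L)
  expect_identical(anyDuplicated(sim$truth$snp_id), 0L)
  n_asoc <- sum(sim$truth$is_asoc)
  expect_lt(abs(n_asoc - 5000), 3 * sqrt(50000 * 0.1 * 0.9))
  # sample-mean oracle computed directly from the emitted counts
  idx <- sim$truth$is_asoc
  frac <- sim$counts$alt_count[idx] /
    (sim$counts$ref_count[idx] + sim$counts$alt_count[idx])
  expect_lt(abs(mean(frac) - 0.75), 3 * sd(frac) / sqrt(length(frac)))
  expect_true(all(sim$truth$theta_true[!idx] == 0.5))
})

test_that("null p-values are calibrated: rejection rate at 0.05 is conservative", {
  sim <- simulate_allelic_counts(sim_config(n_snps = 20000, pi_asoc = 0,
                                            rho = 0, ref_bias = 1, seed = 13))
  p <- binomial_two_sided_p(sim$counts$ref_count, sim$counts$alt_count)
  frac_sig <- mean(p < 0.05)
  expect_lte(frac_sig, 0.05 + 3 * sqrt(0.05 * 0.95 / 20000))
})

test_that("overdispersion strictly inflates allelic-fraction variance at fixed depth", {
  base <- sim_config(n_snps = 10000, depth_model = depth_fixed(50),
                     pi_asoc = 0, rho = 0, seed = 21)
  over <- sim_config(n_snps = 10000, depth_model = depth_fixed(50),
                     pi_asoc = 0, rho = 0.05, seed = 21)
  v0 <- var(simulate_allelic_counts(base)$counts$alt_count / 50)
  v1 <- var(simulate_allelic_counts(over)$counts$alt_count / 50)
  expect_gt(v1, v0)
})

test_that("reference bias shifts the effective allelic fraction as theta/(theta+(1-theta)b)", {
  sim <- simulate_allelic_counts(sim_config(n_snps = 20000, pi_asoc = 0,
                                            rho = 0, ref_bias = 1.3,
                                            seed = 3))
  frac <- sim$counts$alt_count / (sim$counts$ref_count + sim$counts$alt_count)
  expect_lt(abs(mean(frac) - 0.5 / (0.5 + 0.5 * 1.3)),
            3 * sd(frac) / sqrt(length(frac)))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(pi_asoc = 1.2), "pi_asoc")
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(theta_asoc = 0.5), "theta_asoc")
  expect_error(sim_config(ref_bias = 0), "ref_bias")
  expect_error(simulate_allelic_counts(list(n_snps = 5)), "sim_config")
  expect_error(draw_depths <- simulate_allelic_counts(
    sim_config(depth_model = structure(list(family = "bogus"),
                                       class = "asoc_depth_model"))),
    "family")
})

test_that("simulated peaks are disjoint, in bounds, and blacklist planting is exact", {
  ann <- simulate_genome_annotation(n_peaks = 10, peak_width = 500,
                                    chrom_lengths = c(chr1 = 100000),
                                    blacklist_frac = 0, seed = 1)
  expect_identical(nrow(ann$peaks), 10L)
  expect_identical(nrow(ann$blacklist), 0L)
  expect_true(all(ann$peaks$start >= 0 & ann$peaks$end <= 100000))
  o <- order(ann$peaks$start)
  expect_true(all(ann$peaks$start[o][-1] >= ann$peaks$end[o][-10]))

  ann2 <- simulate_genome_annotation(n_peaks = 100, peak_width = 400,
                                     chrom_lengths = c(chr1 = 5e6,
                                                       chr2 = 5e6),
                                     blacklist_frac = 0.2, seed = 4)
  # brute-force pairwise intersection oracle recovers the planted 20 overlaps
  hit <- oracle_overlaps_any(ann2$peaks, ann2$blacklist)
  expect_identical(sum(hit), 20L)
})

test_that("zero peaks and peaks that cannot fit are handled per contract", {
  ann <- simulate_genome_annotation(n_peaks = 0,
                                    chrom_lengths = c(chr1 = 1e5), seed = 2)
  expect_identical(nrow(ann$peaks), 0L)
  expect_error(simulate_genome_annotation(n_peaks = 300, peak_width = 500,
                                          chrom_lengths = c(chr1 = 1e5),
                                          seed = 2),
               "do not fit")
})

test_that("GWAS/LD simulation emits the stated locus and pair structure", {
  g0 <- simulate_gwas_and_ld(n_loci = 0, seed = 1)
  expect_identical(nrow(g0$gwas), 0L)
  expect_identical(nrow(g0$ld), 0L)

  g <- simulate_gwas_and_ld(n_loci = 5, proxies_per_locus = 4,
                            r2_dist = function(n) rep(0.9, n), seed = 2)
  expect_identical(nrow(g$gwas), 5L)
  above <- g$ld[g$ld$r2 >= 0.8, ]
  expect_identical(nrow(above), 20L)          # 5 loci x 4 proxies
  expect_true(all(above$r2 == 0.9))
  expect_true(all(g$ld$r2 >= 0 & g$ld$r2 <= 1))
})

test_that("SNP placement respects frac_in_peaks against a point-in-interval oracle", {
  ann <- simulate_genome_annotation(n_peaks = 50, peak_width = 300,
                                    chrom_lengths = c(chr1 = 2e6), seed = 9)
  cfg <- sim_config(n_snps = 400, frac_in_peaks = 0.5, seed = 9)
  sim <- simulate_allelic_counts(cfg, annotation = ann)
  inside <- oracle_point_in(sim$counts$chrom, sim$counts$pos, ann$peaks)
  expect_identical(sum(inside), 200L)
  expect_identical(inside, sim$truth$in_peak)
})
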
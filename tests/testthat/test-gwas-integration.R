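# LD-proxy expansion, colocalization, ABC target assignment, set enrichment.

test_that("proxy expansion applies the inclusive r2 >= 0.8 threshold", {
  idx <- data.frame(locus_id = "L1", index_snp_id = "A")
  ld <- data.frame(snp_a = c("A", "A", "A"), snp_b = c("B", "C", "D"),
                   r2 = c(0.85, 0.79, 0.80))
  px <- expand_ld_proxies(idx, ld)$proxies
  expect_setequal(px$snp_id, c("A", "B", "D"))   # 0.80 exactly is included
  expect_identical(px$r2[px$snp_id == "A"], 1)
  # symmetrized: pair listed in the other orientation still counts
  ld2 <- data.frame(snp_a = "B", snp_b = "A", r2 = 0.9)
  expect_setequal(expand_ld_proxies(idx, ld2)$proxies$snp_id, c("A", "B"))
})

test_that("an index SNP absent from the LD table keeps a singleton proxy set", {
  idx <- data.frame(locus_id = "L1", index_snp_id = "Z")
  ld <- data.frame(snp_a = "A", snp_b = "B", r2 = 0.9)
  expect_warning(out <- expand_ld_proxies(idx, ld), "absent")
  expect_identical(out$proxies$snp_id, "Z")
  expect_error(expand_ld_proxies(idx, data.frame(snp_a = "A", snp_b = "B",
                                                 r2 = 1.5)), "r2")
})

test_that("proxy sets match an exhaustive scan oracle on random LD tables", {
  set.seed(37)
  snps <- sprintf("v%03d", 1:120)
  idx <- data.frame(locus_id = sprintf("L%02d", 1:50),
                    index_snp_id = sample(snps, 50))
  ld <- data.frame(snp_a = sample(snps, 600, replace = TRUE),
                   snp_b = sample(snps, 600, replace = TRUE),
                   r2 = runif(600))
  ld <- ld[ld$snp_a != ld$snp_b, ]
  out <- suppressWarnings(expand_ld_proxies(idx, ld))
  for (i in seq_len(nrow(idx))) {
    id <- idx$index_snp_id[i]
    oracle <- unique(c(id, ld$snp_b[ld$snp_a == id & ld$r2 >= 0.8],
                       ld$snp_a[ld$snp_b == id & ld$r2 >= 0.8]))
    got <- out$proxies$snp_id[out$proxies$locus_id == idx$locus_id[i]]
    expect_setequal(unique(got), oracle)
  }
})

test_that("colocalization reports planted loci exactly and honors multiplicity", {
  idx <- data.frame(locus_id = c("L1", "L2", "L3"),
                    index_snp_id = c("A", "B", "C"))
  ld <- data.frame(snp_a = c("A", "B", "C", "A"),
                   snp_b = c("rs1", "rs2", "rs3", "rs2"),
                   r2 = c(0.9, 0.9, 0.9, 0.95))
  loci <- expand_ld_proxies(idx, ld)
  rep3 <- colocalize(c("rs1", "rs2", "rs3"), loci)
  expect_identical(rep3$n_loci_with_asoc, 3L)
  expect_identical(rep3$fraction_loci_hit, 1)

  expect_identical(colocalize(character(0), loci)$n_loci_with_asoc, 0L)

  # rs2 proxies both L1 and L2: listed once per locus, not deduplicated
  rep1 <- colocalize("rs2", loci)
  expect_identical(rep1$n_loci_with_asoc, 2L)
  expect_identical(sum(rep1$hits$snp_id == "rs2"), 2L)

  empty <- colocalize("rs1", expand_ld_proxies(idx[0, ], ld))
  expect_identical(empty$n_loci_total, 0L)
  expect_null(empty$fraction_loci_hit)
  expect_match(coloc_report_json(empty), "\"fraction_loci_hit\": null")
})

test_that("colocalization is invariant to locus and SNP order", {
  idx <- data.frame(locus_id = sprintf("L%d", 1:4),
                    index_snp_id = c("A", "B", "C", "D"))
  ld <- data.frame(snp_a = c("A", "B", "C", "D"),
                   snp_b = sprintf("rs%d", 1:4), r2 = 0.9)
  a <- colocalize(c("rs1", "rs3"), expand_ld_proxies(idx, ld))
  b <- colocalize(c("rs3", "rs1"),
                  expand_ld_proxies(idx[4:1, ], ld[sample(4), ]))
  expect_identical(a$n_loci_with_asoc, b$n_loci_with_asoc)
  expect_setequal(a$hits$locus_id, b$hits$locus_id)
})

test_that("ABC target assignment is a point-in-interval join", {
  abc <- data.frame(chrom = "chr1", start = c(100, 100, 900),
                    end = c(200, 200, 1000),
                    target_gene = c("G1", "G2", "G3"),
                    abc_score = c(0.5, 0.3, 0.2))
  snp_in <- data.frame(chrom = "chr1", pos = 150, snp_id = "s1")
  out <- assign_target_genes(snp_in, abc)
  expect_identical(nrow(out), 2L)           # one row per linked gene
  expect_setequal(out$target_gene, c("G1", "G2"))
  snp_out <- data.frame(chrom = "chr1", pos = 500, snp_id = "s2")
  expect_identical(nrow(assign_target_genes(snp_out, abc)), 0L)

  set.seed(41)
  enh <- data.frame(chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
                    start = sample.int(1e5, 50))
  enh$end <- enh$start + 1000
  enh$target_gene <- sprintf("G%02d", 1:50)
  enh$abc_score <- runif(50)
  snps <- data.frame(chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
                     pos = sample.int(1.01e5, 200),
                     snp_id = sprintf("s%03d", 1:200))
  out2 <- assign_target_genes(snps, enh)
  oracle <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
    j <- which(enh$chrom == snps$chrom[i] & enh$start <= snps$pos[i] - 1 &
                 snps$pos[i] - 1 < enh$end)
    if (length(j)) data.frame(snp_id = snps$snp_id[i],
                              target_gene = enh$target_gene[j])
  }))
  expect_identical(nrow(out2), nrow(oracle))
  expect_identical(
    sort(paste(out2$snp_id, out2$target_gene)),
    sort(paste(oracle$snp_id, oracle$target_gene)))
})

test_that("set enrichment fold and Fisher p follow the 2x2 arithmetic", {
  u <- sprintf("x%04d", 1:1000)
  expect_identical(set_enrichment(u, u, u)$fold, 1)          # saturation
  e_ind <- set_enrichment(u[1:100], u[c(1:10, 101:190)], u)  # 10/100 vs 100/1000
  expect_identical(e_ind$fold, 1)
  e4 <- set_enrichment(u[1:50], u[c(1:20, 101:180)], u)
  expect_identical(e4$fold, 4)
  expect_equal(e4$p_value,
               phyper(19, 100, 900, 50, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(set_enrichment(character(0), u[1:5], u), "non-empty")
  expect_error(set_enrichment(c(u[1], "zzz"), u[1:5], u), "subsets")
})

test_that("permutation p converges to the hypergeometric tail", {
  u <- sprintf("x%04d", 1:1000)
  n_perm <- 20000
  ep <- set_enrichment(u[1:50], u[c(1:20, 101:180)], u,
                       method = "permutation", n_perm = n_perm, seed = 5)
  p_hyper <- phyper(19, 100, 900, 50, lower.tail = FALSE)
  mc_se <- sqrt(p_hyper * (1 - p_hyper) / n_perm)
  expect_lt(abs(ep$p_value - p_hyper), 3 * mc_se + 2 / n_perm)
  expect_identical(ep$fold, 4)
})

test_that("enrichment_table reports BH-adjusted q alongside raw p", {
  u <- sprintf("x%04d", 1:1000)
  res <- list(a = set_enrichment(u[1:50], u[c(1:20, 101:180)], u),
              b = set_enrichment(u[1:50], u[51:150], u),
              c = set_enrichment(u[1:50], u[c(1:5, 101:195)], u))
  tab <- enrichment_table(res)
  expect_identical(tab$q_value, bh_adjust(tab$p_value))
  expect_identical(tab$annotation, c("a", "b", "c"))
})
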
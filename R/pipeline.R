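# End-to-end convenience layer: one call to simulate a complete synthetic
# study (counts + annotation + GWAS/LD + ABC links with planted truth) and
# one call to run the full ASoC pipeline over it.

#' Simulate a complete synthetic ASoC study
#'
#' Generates, from a single seed: a genome annotation (peaks, blacklist,
#' TSS), allelic counts with planted ASoC truth placed relative to the
#' peaks, GWAS loci whose first `n_planted_loci` each carry one LD proxy
#' coinciding with a confidently detectable planted ASoC SNP, and an ABC
#' link table in which those same SNPs (`n_planted_abc` of them) each fall
#' inside one enhancer while no other simulated SNP does.
#'
#' "Confidently detectable" means the coincident SNPs are drawn from the
#' planted ASoC SNPs with the largest depth-weighted imbalance, so a correct
#' pipeline recovers every planted locus and ABC link exactly.
#'
#' @param config an [sim_config()] (placement uses its `frac_in_peaks`).
#' @param n_peaks,peak_width,chrom_lengths,blacklist_frac,n_genes passed to
#'   [simulate_genome_annotation()].
#' @param n_loci,proxies_per_locus passed to [simulate_gwas_and_ld()].
#' @param n_planted_loci number of loci given an ASoC-coincident proxy.
#' @param n_abc_links,n_planted_abc passed to [simulate_abc_links()].
#' @return list with `annotation`, `counts`, `truth`, `gwas`, `ld`,
#'   `abc`, `planted_loci` (locus_id, snp_id), `planted_abc`
#'   (snp_id, target_gene), and the `config`.
#' @export
simulate_asoc_dataset <- function(config,
                                  n_peaks = 300,
                                  peak_width = 500,
                                  chrom_lengths = c(chr1 = 50000000,
                                                    chr2 = 40000000),
                                  blacklist_frac = 0.05,
                                  n_genes = 200,
                                  n_loci = 10,
                                  proxies_per_locus = 4,
                                  n_planted_loci = 3,
                                  n_abc_links = 50,
                                  n_planted_abc = 3) {
  ann <- simulate_genome_annotation(n_peaks = n_peaks,
                                    peak_width = peak_width,
                                    chrom_lengths = chrom_lengths,
                                    blacklist_frac = blacklist_frac,
                                    n_genes = n_genes,
                                    seed = config$seed + 1L)
  sim <- simulate_allelic_counts(config, annotation = ann)

  # anchors must survive the whole pipeline: qualification filters, peak
  # cleaning, and FDR calling. Eligible = planted ASoC, min allele count met,
  # inside a non-blacklisted peak; ranked by binomial p so the top anchors
  # carry the strongest imbalance evidence and are always called.
  tr <- sim$truth
  cts <- sim$counts
  cleaned <- clean_peaks(ann$peaks, ann$blacklist)
  in_clean <- rep(FALSE, nrow(cts))
  if (nrow(cleaned) > 0) {
    gr <- harmonize_seqlevels(points_to_granges(cts$chrom, cts$pos),
                              bed_to_granges(cleaned))
    in_clean <- !is.na(GenomicRanges::findOverlaps(gr[[1]], gr[[2]],
                                                   select = "first"))
  }
  cand <- which(tr$is_asoc & in_clean &
                  pmin(cts$ref_count, cts$alt_count) >= 2)
  cand <- cand[order(binomial_two_sided_p(cts$ref_count[cand],
                                          cts$alt_count[cand]))]
  n_anchor <- max(n_planted_loci, n_planted_abc)
  if (length(cand) < n_anchor) {
    stop("not enough planted ASoC SNPs to anchor the requested loci/links; ",
         "raise n_snps or pi_asoc", call. = FALSE)
  }
  anchors <- cts[cand[seq_len(n_anchor)], c("snp_id", "chrom", "pos")]

  gw <- simulate_gwas_and_ld(n_loci = n_loci,
                             proxies_per_locus = proxies_per_locus,
                             seed = config$seed + 2L,
                             planted_asoc = anchors[seq_len(n_planted_loci), ,
                                                    drop = FALSE],
                             chrom_lengths = chrom_lengths)
  abc <- simulate_abc_links(n_links = n_abc_links,
                            planted_snps = anchors[seq_len(n_planted_abc), ,
                                                   drop = FALSE],
                            avoid_snps = cts[, c("chrom", "pos")],
                            genes = ann$tss$gene,
                            chrom_lengths = chrom_lengths,
                            seed = config$seed + 3L)
  list(annotation = ann, counts = cts, truth = tr,
       gwas = gw$gwas, ld = gw$ld, abc = abc$abc,
       planted_loci = gw$planted, planted_abc = abc$planted,
       config = config)
}

#' Run the full ASoC pipeline over a dataset
#'
#' Applies the qualification filters, calls ASoC SNPs at the FDR threshold,
#' cleans peaks against the blacklist, restricts calls to open chromatin,
#' annotates TSS distance, expands GWAS loci to LD proxies, colocalizes the
#' ASoC calls, and assigns ABC target genes to the colocalized risk SNPs.
#'
#' @param dataset list as produced by [simulate_asoc_dataset()], or any list
#'   with the same `counts`/`annotation`/`gwas`/`ld`/`abc` fields loaded
#'   from files.
#' @param fdr_threshold ASoC call threshold (default 0.05).
#' @param r2_threshold LD-proxy threshold (default 0.8).
#' @return list with `filter_report`, `results` (all qualified SNPs),
#'   `results_in_peaks`, `tss_annotation`, `loci`, `coloc`, and
#'   `target_genes` (ABC assignment of the colocalized ASoC SNPs).
#' @export
run_asoc_pipeline <- function(dataset, fdr_threshold = 0.05,
                              r2_threshold = 0.8) {
  filt <- apply_qualification_filters(dataset$counts)
  res <- call_asoc(filt$counts, fdr_threshold = fdr_threshold)

  peaks <- clean_peaks(dataset$annotation$peaks, dataset$annotation$blacklist)
  res_pk <- snps_in_peaks(res, peaks)
  tssann <- annotate_tss_distance(res_pk, dataset$annotation$tss)

  loci <- expand_ld_proxies(dataset$gwas, dataset$ld,
                            r2_threshold = r2_threshold)
  asoc_ids <- res_pk$snp_id[res_pk$is_asoc]
  coloc <- colocalize(asoc_ids, loci)

  risk <- res_pk[res_pk$snp_id %in% coloc$hits$snp_id, , drop = FALSE]
  targets <- assign_target_genes(risk, dataset$abc)

  list(filter_report = filt$report, results = res, results_in_peaks = res_pk,
       tss_annotation = tssann, loci = loci, coloc = coloc,
       target_genes = targets)
}
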
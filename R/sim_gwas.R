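# Synthetic GWAS loci with LD proxies, and activity-by-contact (ABC)
# enhancer-gene link tables, with optional planted coincidences against a
# set of ASoC SNPs for end-to-end recovery experiments.

#' Simulate GWAS index SNPs and an LD-proxy table
#'
#' Emits `n_loci` index SNPs, each with `proxies_per_locus` LD proxies whose
#' r-squared values are drawn from `r2_dist`. For every planted ASoC SNP
#' supplied (up to `n_loci`), one proxy of the corresponding locus is made to
#' coincide with that SNP (same snp_id, chromosome, and position), so that
#' downstream colocalization must report exactly those loci as hit. A matching
#' number of sub-threshold pairs (r-squared drawn below 0.8) is added per
#' locus so that proxy expansion has something to reject.
#'
#' r-squared values are drawn, not derived from haplotypes; this emulates the
#' structure of an LD-proxy table, not population-genetic LD.
#'
#' @param n_loci number of GWAS risk loci (>= 0).
#' @param proxies_per_locus number of above-threshold proxies per locus.
#' @param r2_dist function(n) returning n r-squared values in \[0.8, 1\];
#'   default uniform on \[0.8, 1\].
#' @param seed integer RNG seed.
#' @param planted_asoc optional data.frame (snp_id, chrom, pos) of ASoC SNPs;
#'   the first `min(nrow, n_loci)` are planted as proxies of distinct loci.
#' @param chrom_lengths named vector used to place index SNPs.
#' @return list with `gwas` (data.frame locus_id, index_snp_id, chrom, pos,
#'   p_value), `ld` (data.frame snp_a, snp_b, r2), and `planted`
#'   (data.frame locus_id, snp_id of planted coincidences).
#' @examples
#' g <- simulate_gwas_and_ld(n_loci = 5, proxies_per_locus = 4, seed = 3)
#' nrow(g$ld)
#' @export
simulate_gwas_and_ld <- function(n_loci,
                                 proxies_per_locus = 4,
                                 r2_dist = function(n) runif(n, 0.8, 1),
                                 seed = 1L,
                                 planted_asoc = NULL,
                                 chrom_lengths = c(chr1 = 50000000,
                                                   chr2 = 40000000)) {
  if (n_loci < 0) stop("n_loci must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  empty_gwas <- data.frame(locus_id = character(0),
                           index_snp_id = character(0),
                           chrom = character(0), pos = integer(0),
                           p_value = numeric(0), stringsAsFactors = FALSE)
  empty_ld <- data.frame(snp_a = character(0), snp_b = character(0),
                         r2 = numeric(0), stringsAsFactors = FALSE)
  if (n_loci == 0L) {
    return(list(gwas = empty_gwas, ld = empty_ld,
                planted = data.frame(locus_id = character(0),
                                     snp_id = character(0))))
  }

  chrom <- sample(names(chrom_lengths), n_loci, replace = TRUE)
  gwas <- data.frame(
    locus_id = sprintf("locus%03d", seq_len(n_loci)),
    index_snp_id = sprintf("idx%03d", seq_len(n_loci)),
    chrom = chrom,
    pos = as.integer(floor(runif(n_loci) * chrom_lengths[chrom]) + 1L),
    p_value = 10^-runif(n_loci, 8, 30),
    stringsAsFactors = FALSE)
  rownames(gwas) <- NULL

  n_plant <- if (is.null(planted_asoc)) 0L else min(nrow(planted_asoc), n_loci)
  ld_rows <- vector("list", n_loci)
  planted <- data.frame(locus_id = character(0), snp_id = character(0),
                        stringsAsFactors = FALSE)
  for (i in seq_len(n_loci)) {
    k <- proxies_per_locus
    ids <- sprintf("prx_%03d_%02d", i, seq_len(max(k, 0)))
    r2 <- if (k > 0) r2_dist(k) else numeric(0)
    if (i <= n_plant && k > 0) {
      ids[1] <- planted_asoc$snp_id[i]
      planted <- rbind(planted,
                       data.frame(locus_id = gwas$locus_id[i],
                                  snp_id = ids[1],
                                  stringsAsFactors = FALSE))
    }
    sub_ids <- sprintf("sub_%03d_%02d", i, seq_len(max(k, 0)))
    sub_r2 <- if (k > 0) runif(k, 0.2, 0.79) else numeric(0)
    ld_rows[[i]] <- data.frame(
      snp_a = gwas$index_snp_id[i],
      snp_b = c(ids, sub_ids),
      r2 = c(r2, sub_r2),
      stringsAsFactors = FALSE)
  }
  ld <- do.call(rbind, c(ld_rows, list(empty_ld)))
  rownames(ld) <- NULL
  list(gwas = gwas, ld = ld, planted = planted)
}

#' Simulate an ABC enhancer-gene link table
#'
#' Generates `n_links` enhancer-gene links. For each planted SNP, one
#' enhancer is placed to contain that SNP's position; the remaining
#' enhancers are rejection-sampled so they contain none of the SNPs in
#' `avoid_snps`, making the planted assignments the only ones recoverable.
#'
#' @param n_links total number of (enhancer, gene) rows, >= number planted.
#' @param planted_snps optional data.frame (snp_id, chrom, pos) of SNPs that
#'   must each fall inside one enhancer; the planted gene is recorded.
#' @param avoid_snps optional data.frame (chrom, pos) no unplanted enhancer
#'   may contain.
#' @param genes character vector of candidate target-gene names.
#' @param enhancer_width enhancer width in bp.
#' @param chrom_lengths named vector for enhancer placement.
#' @param seed integer RNG seed.
#' @return list with `abc` (data.frame chrom, start, end, target_gene,
#'   abc_score; 0-based half-open) and `planted` (data.frame snp_id,
#'   target_gene).
#' @examples
#' simulate_abc_links(n_links = 5, seed = 2)$abc
#' @export
simulate_abc_links <- function(n_links,
                               planted_snps = NULL,
                               avoid_snps = NULL,
                               genes = sprintf("GENE%04d", 1:200),
                               enhancer_width = 1000,
                               chrom_lengths = c(chr1 = 50000000,
                                                 chr2 = 40000000),
                               seed = 1L) {
  set.seed(as.integer(seed))
  n_plant <- if (is.null(planted_snps)) 0L else nrow(planted_snps)
  if (n_links < n_plant) stop("n_links must be >= number of planted SNPs",
                              call. = FALSE)
  rows <- vector("list", n_links)
  planted <- data.frame(snp_id = character(0), target_gene = character(0),
                        stringsAsFactors = FALSE)
  for (i in seq_len(n_plant)) {
    # enhancer containing the SNP: 1-based pos p lies in [start, end) iff
    # start <= p - 1 < end
    p0 <- planted_snps$pos[i] - 1L
    start <- max(0L, p0 - as.integer(floor(runif(1) * enhancer_width)))
    g <- sample(genes, 1L)
    rows[[i]] <- data.frame(chrom = planted_snps$chrom[i],
                            start = as.integer(start),
                            end = as.integer(start + enhancer_width),
                            target_gene = g,
                            abc_score = round(runif(1, 0.02, 0.9), 4),
                            stringsAsFactors = FALSE)
    planted <- rbind(planted,
                     data.frame(snp_id = planted_snps$snp_id[i],
                                target_gene = g, stringsAsFactors = FALSE))
  }
  avoid_gr <- if (!is.null(avoid_snps) && nrow(avoid_snps)) {
    points_to_granges(avoid_snps$chrom, avoid_snps$pos)
  } else {
    GenomicRanges::GRanges()
  }
  for (i in seq_len(n_links - n_plant)) {
    repeat {
      ch <- sample(names(chrom_lengths), 1L)
      start <- as.integer(floor(runif(1) *
                                  (chrom_lengths[ch] - enhancer_width)))
      cand <- data.frame(chrom = ch, start = start,
                         end = start + as.integer(enhancer_width))
      if (length(avoid_gr) == 0L) break
      gr <- harmonize_seqlevels(bed_to_granges(cand), avoid_gr)
      if (!any(IRanges::overlapsAny(gr[[1]], gr[[2]]))) break
    }
    rows[[n_plant + i]] <- data.frame(chrom = ch, start = cand$start,
                                      end = cand$end,
                                      target_gene = sample(genes, 1L),
                                      abc_score = round(runif(1, 0.02, 0.9), 4),
                                      stringsAsFactors = FALSE)
  }
  abc <- do.call(rbind, c(rows, list(
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               target_gene = character(0), abc_score = numeric(0),
               stringsAsFactors = FALSE))))
  rownames(abc) <- NULL
  list(abc = abc, planted = planted)
}
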
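# GWAS integration: LD-proxy expansion of index SNPs, colocalization of
# ASoC SNPs with risk loci, ABC enhancer-to-gene target assignment, and
# simple Fisher/permutation set enrichment.

#' Expand GWAS index SNPs to their LD proxies
#'
#' For each index SNP, the proxy set is the index itself (r2 = 1) plus every
#' SNP whose pairwise r-squared with the index meets the inclusive threshold
#' (default r2 >= 0.8). The LD table is symmetrized on load, so pairs may be
#' listed in either orientation. An index SNP absent from the LD table keeps
#' a singleton proxy set and triggers a warning.
#'
#' @param index_snps data.frame with `locus_id`, `index_snp_id` (and
#'   optionally `chrom`, `pos`, `p_value`), one row per GWAS risk locus.
#' @param ld_table data.frame with `snp_a`, `snp_b`, `r2`.
#' @param r2_threshold inclusive r-squared cutoff, default 0.8.
#' @return an `asoc_gwas_loci` list: `loci` (the input table) and `proxies`
#'   (data.frame `locus_id`, `snp_id`, `r2`, index rows included with
#'   r2 = 1).
#' @examples
#' idx <- data.frame(locus_id = "L1", index_snp_id = "A")
#' ld <- data.frame(snp_a = c("A", "A"), snp_b = c("B", "C"),
#'                  r2 = c(0.85, 0.79))
#' expand_ld_proxies(idx, ld)$proxies  # A and B; C falls below 0.8
#' @export
expand_ld_proxies <- function(index_snps, ld_table, r2_threshold = 0.8) {
  if (any(ld_table$r2 < 0 | ld_table$r2 > 1)) {
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  }
  sym <- rbind(
    data.frame(a = ld_table$snp_a, b = ld_table$snp_b, r2 = ld_table$r2,
               stringsAsFactors = FALSE),
    data.frame(a = ld_table$snp_b, b = ld_table$snp_a, r2 = ld_table$r2,
               stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(index_snps)), function(i) {
    idx <- index_snps$index_snp_id[i]
    hits <- sym[sym$a == idx & sym$r2 >= r2_threshold, , drop = FALSE]
    if (!any(sym$a == idx)) {
      warning("index SNP ", idx, " absent from LD table; proxy set is the ",
              "index alone", call. = FALSE)
    }
    hits <- hits[hits$b != idx, , drop = FALSE]
    data.frame(locus_id = index_snps$locus_id[i],
               snp_id = c(idx, hits$b),
               r2 = c(1, hits$r2),
               stringsAsFactors = FALSE)
  })
  proxies <- do.call(rbind, c(rows, list(
    data.frame(locus_id = character(0), snp_id = character(0),
               r2 = numeric(0), stringsAsFactors = FALSE))))
  rownames(proxies) <- NULL
  structure(list(loci = index_snps, proxies = proxies),
            class = "asoc_gwas_loci")
}

#' Colocalize ASoC SNPs with GWAS risk loci
#'
#' A locus is "hit" when at least one member of its proxy set (index SNP or
#' LD proxy) is an ASoC SNP. Every (locus, ASoC SNP) co-occurrence is
#' reported; an ASoC SNP that proxies several loci appears once per locus,
#' not deduplicated.
#'
#' @param asoc_snp_ids character vector of ASoC SNP identifiers (typically
#'   `is_asoc == TRUE` rows of [call_asoc()] output; restricting to called
#'   SNPs is the caller's choice).
#' @param loci an `asoc_gwas_loci` object from [expand_ld_proxies()].
#' @return an `asoc_coloc_report` list: `n_loci_total`, `n_loci_with_asoc`,
#'   `fraction_loci_hit` (`NULL` when there are no loci), and `hits`
#'   (data.frame `locus_id`, `snp_id`, `r2`).
#' @export
colocalize <- function(asoc_snp_ids, loci) {
  if (!inherits(loci, "asoc_gwas_loci")) {
    stop("loci must come from expand_ld_proxies()", call. = FALSE)
  }
  n_total <- nrow(loci$loci)
  hits <- loci$proxies[loci$proxies$snp_id %in% asoc_snp_ids, , drop = FALSE]
  rownames(hits) <- NULL
  n_hit <- length(unique(hits$locus_id))
  structure(list(
    n_loci_total = n_total,
    n_loci_with_asoc = n_hit,
    fraction_loci_hit = if (n_total > 0) n_hit / n_total else NULL,
    hits = hits), class = "asoc_coloc_report")
}

#' @export
print.asoc_coloc_report <- function(x, ...) {
  frac <- if (is.null(x$fraction_loci_hit)) "undefined"
          else sprintf("%.1f%%", 100 * x$fraction_loci_hit)
  cat(sprintf(
    "GWAS colocalization: %d of %d loci with >= 1 ASoC SNP (%s); %d ASoC/GWAS SNP pairs\n",
    x$n_loci_with_asoc, x$n_loci_total, frac, nrow(x$hits)))
  invisible(x)
}

#' Serialize a colocalization report to JSON
#'
#' @param report an `asoc_coloc_report`.
#' @return JSON string.
#' @export
coloc_report_json <- function(report) {
  jsonlite::toJSON(list(n_loci_total = report$n_loci_total,
                        n_loci_with_asoc = report$n_loci_with_asoc,
                        fraction_loci_hit = report$fraction_loci_hit,
                        hits = report$hits),
                   auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Assign target genes to SNPs through ABC enhancer-gene links
#'
#' A SNP is assigned gene G when its position falls inside an enhancer
#' linked to G (point-in-interval on the half-open enhancer). A SNP inside
#' enhancers linked to several genes yields one row per link; a SNP outside
#' all enhancers yields none.
#'
#' @param snps data.frame with `chrom`, `pos` (1-based), `snp_id`.
#' @param abc_links data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), `target_gene`, `abc_score`.
#' @return data.frame `snp_id`, `target_gene`, `abc_score`.
#' @export
assign_target_genes <- function(snps, abc_links) {
  empty <- data.frame(snp_id = character(0), target_gene = character(0),
                      abc_score = numeric(0), stringsAsFactors = FALSE)
  if (nrow(snps) == 0L || nrow(abc_links) == 0L) return(empty)
  gr <- harmonize_seqlevels(points_to_granges(snps$chrom, snps$pos),
                            bed_to_granges(abc_links))
  ov <- GenomicRanges::findOverlaps(gr[[1]], gr[[2]])
  if (length(ov) == 0L) return(empty)
  data.frame(snp_id = snps$snp_id[S4Vectors::queryHits(ov)],
             target_gene = abc_links$target_gene[S4Vectors::subjectHits(ov)],
             abc_score = abc_links$abc_score[S4Vectors::subjectHits(ov)],
             stringsAsFactors = FALSE)
}

#' Simple set enrichment of ASoC SNPs in an annotation set
#'
#' Fold enrichment of set A (e.g. ASoC SNPs) in set B (an annotation) over a
#' universe U:
#' \deqn{\mathrm{fold} = \frac{|A \cap B| / |A|}{|B| / |U|}.}
#' The p-value is either the one-sided Fisher exact test on the 2x2 table
#' (equivalently the hypergeometric upper tail) or a permutation p obtained
#' by resampling |A|-sized sets from U with a fixed seed. This is plain
#' set-overlap plumbing — a transparency check, not a reimplementation of the
#' hierarchical GWAS-enrichment models used for chromatin annotations.
#'
#' @param asoc_set,annotation_set character vectors, subsets of `universe`.
#' @param universe character vector of all eligible items.
#' @param method `"fisher"` or `"permutation"`.
#' @param n_perm number of permutations for `method = "permutation"`.
#' @param seed RNG seed for the permutation draw.
#' @return list with `fold`, `p_value`, `overlap`, `n_asoc`, `n_annotation`,
#'   `n_universe`, and `method`.
#' @examples
#' u <- sprintf("s%04d", 1:1000)
#' set_enrichment(u[1:50], u[c(1:20, 101:180)], u)$fold  # 4-fold
#' @export
set_enrichment <- function(asoc_set, annotation_set, universe,
                           method = c("fisher", "permutation"),
                           n_perm = 10000, seed = 1L) {
  method <- match.arg(method)
  asoc_set <- unique(asoc_set)
  annotation_set <- unique(annotation_set)
  universe <- unique(universe)
  if (length(universe) == 0L || length(asoc_set) == 0L) {
    stop("universe and asoc_set must be non-empty", call. = FALSE)
  }
  if (!all(asoc_set %in% universe) || !all(annotation_set %in% universe)) {
    stop("asoc_set and annotation_set must be subsets of the universe",
         call. = FALSE)
  }
  nA <- length(asoc_set); nB <- length(annotation_set); nU <- length(universe)
  k <- length(intersect(asoc_set, annotation_set))
  fold <- if (nB == 0L) NA_real_ else (k / nA) / (nB / nU)
  p <- if (method == "fisher") {
    tab <- matrix(c(k, nA - k, nB - k, nU - nA - nB + k), nrow = 2)
    fisher.test(tab, alternative = "greater")$p.value
  } else {
    set.seed(as.integer(seed))
    in_b <- universe %in% annotation_set
    sims <- vapply(seq_len(n_perm),
                   function(i) sum(in_b[sample.int(nU, nA)]), integer(1))
    (1 + sum(sims >= k)) / (n_perm + 1)
  }
  list(fold = fold, p_value = p, overlap = k, n_asoc = nA,
       n_annotation = nB, n_universe = nU, method = method)
}

#' BH adjustment across several enrichment tests
#'
#' Convenience wrapper: given a list of [set_enrichment()] results, returns a
#' table of folds and raw p-values with a BH-adjusted column.
#'
#' @param results named list of [set_enrichment()] results.
#' @return data.frame `annotation`, `fold`, `p_value`, `q_value`.
#' @export
enrichment_table <- function(results) {
  p <- vapply(results, `[[`, numeric(1), "p_value")
  data.frame(annotation = names(results),
             fold = vapply(results, `[[`, numeric(1), "fold"),
             p_value = p,
             q_value = bh_adjust(p),
             stringsAsFactors = FALSE, row.names = NULL)
}
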
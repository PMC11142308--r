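# ASoC calling: exact binomial allelic-imbalance test, BH correction across
# all qualified SNPs, calls at an FDR threshold; reference-bias QC and
# cross-cell-type sharing summaries.

#' Call allele-specific open chromatin SNPs
#'
#' Tests every qualified SNP for allelic imbalance with the exact two-sided
#' binomial test against a null allelic fraction of 0.5
#' ([binomial_two_sided_p()]), adjusts the p-values across exactly the input
#' set with Benjamini-Hochberg ([bh_adjust()]), and calls a SNP ASoC when its
#' adjusted value falls strictly below `fdr_threshold`.
#'
#' The adjustment is computed over the SNPs supplied in one call — i.e. per
#' cell type when the caller analyses cell types separately; never pool SNPs
#' from different cell types into one call if per-cell-type FDR is wanted.
#' `allelic_ratio` is `ref_count / depth` (the reference-allele fraction),
#' matching the volcano-plot convention of [reference_bias_qc()].
#'
#' @param counts data.frame of qualified allelic counts (output of
#'   [apply_qualification_filters()]).
#' @param fdr_threshold FDR call threshold, default 0.05; the call rule is
#'   the strict inequality `q_value < fdr_threshold`.
#' @return data.frame with the input identification columns plus `depth`,
#'   `allelic_ratio`, `p_value`, `q_value`, and logical `is_asoc`.
#' @examples
#' sim <- simulate_allelic_counts(sim_config(n_snps = 500, pi_asoc = 0.1,
#'   theta_asoc = 0.8, seed = 2))
#' res <- call_asoc(sim$counts)
#' table(res$is_asoc)
#' @export
call_asoc <- function(counts, fdr_threshold = 0.05) {
  depth <- counts$ref_count + counts$alt_count
  if (any(depth < 1)) {
    stop("zero-depth SNP supplied; qualification filters must run first",
         call. = FALSE)
  }
  p <- binomial_two_sided_p(counts$ref_count, counts$alt_count)
  q <- bh_adjust(p)
  res <- counts[, intersect(c("chrom", "pos", "snp_id", "ref", "alt",
                              "ref_count", "alt_count"), names(counts)),
                drop = FALSE]
  res$depth <- depth
  res$allelic_ratio <- counts$ref_count / depth
  res$p_value <- p
  res$q_value <- q
  res$is_asoc <- q < fdr_threshold
  rownames(res) <- NULL
  res
}

#' Reference-mapping-bias QC from allelic ratios
#'
#' Summarizes the distribution of reference-allele ratios across tested SNPs
#' the way a volcano plot (allelic ratio vs. -log2 p) is read: with no
#' mapping bias the cloud is centred on 0.5. Returns the pooled mean ratio
#' and its standard error, the count-weighted ratio (total reference reads
#' over total depth), a table ready for volcano plotting, and a bias flag
#' raised when the pooled mean deviates from 0.5 by more than `margin`.
#'
#' @param results data.frame from [call_asoc()] (at least one row).
#' @param margin absolute deviation of the pooled mean ratio from 0.5 that
#'   triggers the flag (default 0.02).
#' @return an `asoc_bias_qc` list: `n`, `mean_ratio`, `se_ratio`,
#'   `weighted_ratio`, `margin`, `biased` (logical), and `volcano`
#'   (data.frame snp_id, allelic_ratio, neg_log2_p).
#' @export
reference_bias_qc <- function(results, margin = 0.02) {
  if (nrow(results) < 1L) stop("need at least one result", call. = FALSE)
  r <- results$allelic_ratio
  mean_ratio <- mean(r)
  se_ratio <- if (length(r) > 1) sd(r) / sqrt(length(r)) else NA_real_
  weighted <- sum(results$ref_count) / sum(results$depth)
  structure(list(
    n = nrow(results),
    mean_ratio = mean_ratio,
    se_ratio = se_ratio,
    weighted_ratio = weighted,
    margin = margin,
    biased = abs(mean_ratio - 0.5) > margin,
    volcano = data.frame(snp_id = results$snp_id,
                         allelic_ratio = r,
                         neg_log2_p = -log2(results$p_value),
                         stringsAsFactors = FALSE)),
    class = "asoc_bias_qc")
}

#' @export
print.asoc_bias_qc <- function(x, ...) {
  cat(sprintf(
    "Reference-bias QC over %d SNPs\n  pooled mean allelic ratio: %.4f (SE %.4g)\n  count-weighted ratio     : %.4f\n  bias flag (|mean - 0.5| > %.3g): %s\n",
    x$n, x$mean_ratio, x$se_ratio, x$weighted_ratio, x$margin,
    if (x$biased) "BIASED" else "ok"))
  invisible(x)
}

#' Cross-cell-type sharing of ASoC SNPs
#'
#' Given per-cell-type ASoC SNP sets, counts SNPs by exact membership
#' pattern (the cells of a Venn diagram). Every non-empty subset of cell
#' types is reported, and the pattern counts partition the union of all sets.
#'
#' @param sets named list of character vectors of ASoC snp_ids, one per cell
#'   type.
#' @return data.frame with `pattern` (cell-type names joined by `"+"`),
#'   `n_celltypes`, and `count`; rows cover all non-empty subsets.
#' @examples
#' cross_celltype_sharing(list(iMG = c("a", "b", "c"), iAst = c("b", "c", "d")))
#' @export
cross_celltype_sharing <- function(sets) {
  if (length(sets) < 1L) stop("need at least one cell type", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a named list", call. = FALSE)
  }
  sets <- lapply(sets, unique)
  univ <- unique(unlist(sets, use.names = FALSE))
  k <- length(sets)
  membership <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) membership <- matrix(membership, nrow = 1)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(subsets) <- names(sets)
  counts <- apply(subsets, 1, function(mask) {
    sum(apply(membership, 1, function(m) all(m == mask)))
  })
  data.frame(
    pattern = apply(subsets, 1, function(mask) {
      paste(names(sets)[as.logical(mask)], collapse = "+")
    }),
    n_celltypes = rowSums(subsets),
    count = as.integer(counts),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write ASoC results to TSV (and optionally BED)
#'
#' @param results data.frame from [call_asoc()].
#' @param path output TSV path.
#' @param bed_path optional path for a BED file of ASoC SNP positions
#'   (0-based half-open single-base intervals, only `is_asoc` rows).
#' @return `path`, invisibly.
#' @export
write_asoc_results <- function(results, path, bed_path = NULL) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    hits <- results[results$is_asoc, , drop = FALSE]
    bed <- data.frame(chrom = hits$chrom, start = hits$pos - 1L,
                      end = hits$pos, name = hits$snp_id)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
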
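# Genomic context: BED/narrowPeak input, blacklist-aware peak cleaning,
# restriction of SNPs to open-chromatin peaks, and TSS-distance annotation.
# Intervals are BED-style (0-based, half-open) at the interface; overlap
# queries run on GenomicRanges internally.

#' Read a BED or narrowPeak file of intervals
#'
#' @param path input path.
#' @param format `"bed"` (3+ columns) or `"narrowPeak"` (BED6+4; the extra
#'   columns are preserved but unused downstream).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `name` when present.
#' @export
read_bed <- function(path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  gr <- tryCatch({
    if (format == "narrowPeak") {
      rtracklayer::import(path, format = "BED",
                          extraCols = c(signalValue = "numeric",
                                        pValue = "numeric",
                                        qValue = "numeric",
                                        peak = "integer"))
    } else {
      rtracklayer::import(path, format = "BED")
    }
  }, error = function(e) {
    stop("parse error reading ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% names(mc)) df$name <- mc$name
  df
}

#' Read a TSS annotation table
#'
#' Tab-separated with header columns `chrom`, `tss_pos` (1-based), `gene`,
#' `strand`.
#'
#' @param path input path.
#' @return data.frame of TSS records.
#' @export
read_tss <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("chrom", "tss_pos", "gene")
  if (!all(need %in% names(df))) {
    stop("schema error in ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df
}

#' Remove blacklisted and excluded-chromosome peaks
#'
#' Drops every peak that overlaps a blacklist interval by at least 1 bp
#' (peaks are removed whole, never trimmed) and every peak on an excluded
#' chromosome (sex chromosomes, mitochondrial genome, decoy/patch contigs).
#' The result is sorted by (chrom, start). Idempotent.
#'
#' @param peaks data.frame of peaks (chrom, start, end, ...), 0-based
#'   half-open.
#' @param blacklist optional data.frame of blacklist intervals, same
#'   convention.
#' @param excluded_chroms chromosome names (either dialect) to drop.
#' @return the retained peaks, sorted.
#' @examples
#' pk <- data.frame(chrom = "chr1", start = c(100, 800), end = c(600, 900))
#' bl <- data.frame(chrom = "chr1", start = 599, end = 700)
#' clean_peaks(pk, bl)  # first peak overlaps by 1 bp and is dropped
#' @export
clean_peaks <- function(peaks, blacklist = NULL,
                        excluded_chroms = c("X", "Y", "MT")) {
  keep <- !(norm_chrom(peaks$chrom) %in% norm_chrom(excluded_chroms)) &
    !is_decoy_chrom(peaks$chrom)
  if (!is.null(blacklist) && nrow(blacklist) > 0 && any(keep)) {
    gr <- harmonize_seqlevels(bed_to_granges(peaks),
                              bed_to_granges(blacklist))
    hit <- IRanges::overlapsAny(gr[[1]], gr[[2]])
    keep <- keep & !hit
  }
  out <- peaks[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict SNPs to open-chromatin peaks
#'
#' A SNP at 1-based position p lies inside the half-open peak \[s, e) iff
#' `s <= p - 1 < e`. Each retained SNP is annotated with the identifier of
#' one containing peak — the first by (chrom, start) sort order when peaks
#' are nested or overlapping.
#'
#' @param snps data.frame with `chrom` and `pos` (1-based) columns, e.g.
#'   [call_asoc()] output.
#' @param peaks data.frame of peaks (chrom, start, end\[, name\]), 0-based
#'   half-open.
#' @return the subset of `snps` falling in a peak, with a `peak_id` column
#'   (peak `name` when present, otherwise `chrom:start-end`).
#' @export
snps_in_peaks <- function(snps, peaks) {
  if (nrow(peaks) == 0L || nrow(snps) == 0L) {
    out <- snps[integer(0), , drop = FALSE]
    out$peak_id <- character(0)
    return(out)
  }
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  gr <- harmonize_seqlevels(points_to_granges(snps$chrom, snps$pos),
                            bed_to_granges(peaks))
  hit <- GenomicRanges::findOverlaps(gr[[1]], gr[[2]], select = "first")
  keep <- !is.na(hit)
  out <- snps[keep, , drop = FALSE]
  pid <- if ("name" %in% names(peaks)) {
    peaks$name
  } else {
    sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  }
  out$peak_id <- pid[hit[keep]]
  rownames(out) <- NULL
  out
}

#' Annotate SNPs by distance to the nearest TSS
#'
#' Computes the strand-agnostic point distance `|pos - tss_pos|` to the
#' nearest TSS on the same chromosome and bins it: distance <= 5 kb is
#' `promoter_proximal` ("within 5 kb", inclusive), distance > 50 kb is
#' `distal`, anything between is `intermediate`. SNPs on chromosomes with no
#' TSS are returned with `NA` gene/distance and category `unannotated`.
#'
#' @param snps data.frame with `chrom`, `pos`, `snp_id`.
#' @param tss data.frame with `chrom`, `tss_pos` (1-based), `gene`.
#' @param promoter_cutoff inclusive promoter-proximal distance bound (bp).
#' @param distal_cutoff exclusive lower bound of the distal bin (bp).
#' @return data.frame `snp_id`, `nearest_gene`, `distance_bp`, `category`.
#' @export
annotate_tss_distance <- function(snps, tss, promoter_cutoff = 5000,
                                  distal_cutoff = 50000) {
  n <- nrow(snps)
  out <- data.frame(snp_id = snps$snp_id,
                    nearest_gene = rep(NA_character_, n),
                    distance_bp = rep(NA_real_, n),
                    category = rep("unannotated", n),
                    stringsAsFactors = FALSE)
  if (n == 0L || nrow(tss) == 0L) return(out)
  gr <- harmonize_seqlevels(points_to_granges(snps$chrom, snps$pos),
                            points_to_granges(tss$chrom, tss$tss_pos))
  idx <- GenomicRanges::nearest(gr[[1]], gr[[2]])
  ok <- !is.na(idx)
  out$nearest_gene[ok] <- tss$gene[idx[ok]]
  out$distance_bp[ok] <- abs(snps$pos[ok] - tss$tss_pos[idx[ok]])
  d <- out$distance_bp[ok]
  out$category[ok] <- ifelse(d <= promoter_cutoff, "promoter_proximal",
                             ifelse(d > distal_cutoff, "distal",
                                    "intermediate"))
  out
}
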
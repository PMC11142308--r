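# Synthetic genome annotation: non-overlapping peaks, planted blacklist
# overlaps, and TSS positions. All intervals are BED-style (0-based,
# half-open); TSS positions are 1-based points.

#' Simulate peaks, blacklist regions, and TSS annotation
#'
#' Places `n_peaks` non-overlapping peaks of width `peak_width` on the given
#' chromosomes, plants blacklist intervals overlapping a stated fraction of
#' them, and scatters TSS positions for a synthetic gene set.
#'
#' @param n_peaks total number of peaks.
#' @param peak_width peak width in bp.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param blacklist_frac fraction of peaks overlapped by a planted blacklist
#'   interval (each planted interval overlaps exactly one peak).
#' @param n_genes number of TSS records to emit.
#' @param seed integer RNG seed.
#' @return list with `peaks` (data.frame chrom, start, end, name: 0-based
#'   half-open, disjoint, sorted), `blacklist` (same columns),
#'   `tss` (data.frame chrom, tss_pos 1-based, gene, strand), and
#'   `chrom_lengths`.
#' @examples
#' ann <- simulate_genome_annotation(n_peaks = 10, peak_width = 500,
#'   chrom_lengths = c(chr1 = 100000), blacklist_frac = 0, seed = 1)
#' ann$peaks
#' @export
simulate_genome_annotation <- function(n_peaks,
                                       peak_width = 500,
                                       chrom_lengths = c(chr1 = 50000000,
                                                         chr2 = 40000000),
                                       blacklist_frac = 0,
                                       n_genes = 200,
                                       seed = 1L) {
  if (n_peaks < 0 || peak_width < 1) {
    stop("n_peaks must be >= 0 and peak_width >= 1", call. = FALSE)
  }
  stop_if_not_scalar_prob(blacklist_frac, "blacklist_frac")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector", call. = FALSE)
  }
  set.seed(as.integer(seed))

  # allocate peaks to chromosomes proportionally to length
  n_per <- if (n_peaks > 0) {
    as.vector(table(factor(sample(names(chrom_lengths), n_peaks,
                                  replace = TRUE,
                                  prob = chrom_lengths / sum(chrom_lengths)),
                           levels = names(chrom_lengths))))
  } else {
    rep(0L, length(chrom_lengths))
  }
  peak_list <- lapply(seq_along(chrom_lengths), function(i) {
    k <- n_per[i]
    if (k == 0L) return(NULL)
    L <- chrom_lengths[i]
    slack <- L - k * peak_width
    if (slack < 0 || slack + 1 < k) {
      stop("requested peaks do not fit chromosome ",
           names(chrom_lengths)[i], call. = FALSE)
    }
    starts <- sort(sample.int(slack + 1, k) - 1) +
      (seq_len(k) - 1L) * peak_width
    data.frame(chrom = names(chrom_lengths)[i], start = as.integer(starts),
               end = as.integer(starts + peak_width),
               stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, c(peak_list,
                            list(data.frame(chrom = character(0),
                                            start = integer(0),
                                            end = integer(0)))))
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks$name <- if (nrow(peaks)) sprintf("peak%05d", seq_len(nrow(peaks)))
                else character(0)

  # plant blacklist intervals over a chosen subset of peaks, each covering
  # the peak midpoint so the overlap is guaranteed (>= 1 bp)
  n_black <- round(blacklist_frac * nrow(peaks))
  if (n_black > 0) {
    bidx <- sample.int(nrow(peaks), n_black)
    mid <- (peaks$start[bidx] + peaks$end[bidx]) %/% 2L
    blacklist <- data.frame(chrom = peaks$chrom[bidx],
                            start = as.integer(pmax(0L, mid - 50L)),
                            end = as.integer(mid + 50L),
                            name = sprintf("blk%04d", seq_len(n_black)),
                            stringsAsFactors = FALSE)
    blacklist <- blacklist[order(blacklist$chrom, blacklist$start), ,
                           drop = FALSE]
    rownames(blacklist) <- NULL
  } else {
    blacklist <- data.frame(chrom = character(0), start = integer(0),
                            end = integer(0), name = character(0),
                            stringsAsFactors = FALSE)
  }

  tss_chrom <- sample(names(chrom_lengths), n_genes, replace = TRUE,
                      prob = chrom_lengths / sum(chrom_lengths))
  tss <- data.frame(chrom = tss_chrom,
                    tss_pos = as.integer(floor(runif(n_genes) *
                                                 chrom_lengths[tss_chrom]) + 1L),
                    gene = sprintf("GENE%04d", seq_len(n_genes)),
                    strand = sample(c("+", "-"), n_genes, replace = TRUE),
                    stringsAsFactors = FALSE)
  rownames(tss) <- NULL

  list(peaks = peaks, blacklist = blacklist, tss = tss,
       chrom_lengths = chrom_lengths)
}
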
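# Shared helpers: chromosome-name normalization and small validators.

#' Normalize chromosome names to a single dialect
#'
#' Strips a leading `"chr"` prefix and maps the mitochondrial aliases
#' `"M"`/`"MT"` to `"MT"`, so that `"chrX"` and `"X"` (and `"chrM"`, `"MT"`)
#' compare equal. Used internally wherever chromosome names from mixed
#' BED/VCF sources meet.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of normalized names.
#' @examples
#' norm_chrom(c("chr1", "1", "chrM", "MT", "chrX"))
#' @export
norm_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  x[x == "M"] <- "MT"
  x
}

# Decoy/patch contigs carry underscores (e.g. chr1_KI270706v1_random,
# chrUn_..., hs37d5) in common references.
is_decoy_chrom <- function(chrom) {
  grepl("_", chrom) | grepl("decoy", chrom, ignore.case = TRUE) |
    norm_chrom(chrom) %in% c("hs37d5", "EBV", "Un")
}

stop_if_not_scalar_prob <- function(x, name, open_right = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      (if (open_right) x >= 1 else x > 1)) {
    stop(name, " must be a single number in [0,1",
         if (open_right) ")" else "]", call. = FALSE)
  }
  invisible(x)
}

# data.frame (chrom, start, end) in BED convention (0-based, half-open)
# -> GRanges (1-based, closed), chromosome names normalized.
bed_to_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  if (any(df$start >= df$end)) {
    stop("invalid interval: start must be < end (0-based half-open)",
         call. = FALSE)
  }
  GenomicRanges::GRanges(
    seqnames = norm_chrom(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Put two GRanges on the union of their seqlevels so cross-chromosome
# queries are silent no-matches rather than seqinfo warnings.
harmonize_seqlevels <- function(a, b) {
  sl <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- sl
  GenomeInfoDb::seqlevels(b) <- sl
  list(a, b)
}

# 1-based point positions -> GRanges of width-1 ranges.
points_to_granges <- function(chrom, pos) {
  if (length(pos) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = norm_chrom(chrom),
    ranges = IRanges::IRanges(start = pos, width = 1L)
  )
}
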
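# Reading/writing allelic-count tables (TSV and minimal VCF) and the SNP
# qualification filters applied before ASoC testing.

COUNT_COLS <- c("chrom", "pos", "snp_id", "ref", "alt",
                "ref_count", "alt_count", "genotype")

#' Read a table of heterozygous-SNP allelic counts
#'
#' Reads per-SNP allelic read counts from either a tab-separated table with
#' columns `chrom, pos, snp_id, ref, alt, ref_count, alt_count, genotype`
#' (and optionally `in_dbsnp`), or a single-sample VCF whose genotype field
#' carries `GT` and allelic depths `AD`. Positions are 1-based in both
#' formats. For VCF input, `ref_count`/`alt_count` are the first two AD
#' entries and `in_dbsnp` is `TRUE` when the ID column carries an rs
#' identifier (not `"."`).
#'
#' @param path path to the input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return data.frame of allelic counts with the columns above plus
#'   `in_dbsnp` (logical).
#' @seealso [write_counts()], [apply_qualification_filters()]
#' @export
read_counts <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") read_counts_tsv(path) else read_counts_vcf(path)
}

read_counts_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character", comment.char = "",
                   quote = "", stringsAsFactors = FALSE)
  missing_cols <- setdiff(COUNT_COLS, names(df))
  if (length(missing_cols)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("pos", "ref_count", "alt_count")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("parse error in ", path, " at line ", bad[1] + 1L,
           ": non-integer value '", df[[col]][bad[1]], "' in column ", col,
           call. = FALSE)
    }
    df[[col]] <- v
  }
  if (any(df$ref_count < 0) || any(df$alt_count < 0)) {
    stop("parse error in ", path, ": negative read count", call. = FALSE)
  }
  df$in_dbsnp <- if ("in_dbsnp" %in% names(df)) {
    as.logical(df$in_dbsnp)
  } else {
    rep(TRUE, nrow(df))
  }
  df[, c(COUNT_COLS, "in_dbsnp")]
}

read_counts_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (ncol(vcf) != 1L) {
    stop("expected a single-sample VCF, found ", ncol(vcf), " samples",
         call. = FALSE)
  }
  geno <- VariantAnnotation::geno(vcf)
  if (!all(c("GT", "AD") %in% names(geno))) {
    stop("schema error: VCF must carry GT and AD genotype fields",
         call. = FALSE)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ad <- geno$AD[, 1]
  if (is.matrix(ad)) ad <- lapply(seq_len(nrow(ad)), function(i) ad[i, ])
  ref_count <- vapply(ad, function(x) as.integer(x[1]), integer(1))
  alt_count <- vapply(ad, function(x) as.integer(x[2]), integer(1))
  ids <- names(rr)
  alt <- vapply(as.list(rr$ALT), function(a) as.character(a)[1], "")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    snp_id = ids,
    ref = as.character(rr$REF),
    alt = alt,
    ref_count = ref_count,
    alt_count = alt_count,
    genotype = as.character(geno$GT[, 1]),
    in_dbsnp = grepl("^rs", ids),
    stringsAsFactors = FALSE)
}

#' Write allelic counts to TSV or minimal VCF
#'
#' The TSV writer emits the canonical column set; the VCF writer emits a
#' minimal single-sample VCFv4.2 with `GT:AD` genotype fields, using the
#' snp_id as the ID column (so dbSNP membership survives a round trip via the
#' rs-prefix convention).
#'
#' @param counts data.frame as returned by [read_counts()] or
#'   [simulate_allelic_counts()].
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @param sample_name sample column name for VCF output.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "vcf"),
                         sample_name = "sample1") {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(counts[, c(COUNT_COLS, "in_dbsnp")], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    chroms <- unique(counts$chrom)
    header <- c(
      "##fileformat=VCFv4.2",
      sprintf("##contig=<ID=%s>", chroms),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", sample_name), collapse = "\t"))
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT:AD\t%s:%d,%d",
                    counts$chrom, counts$pos,
                    ifelse(counts$in_dbsnp, counts$snp_id, "."),
                    counts$ref, counts$alt, counts$genotype,
                    counts$ref_count, counts$alt_count)
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Apply SNP qualification filters
#'
#' Retains biallelic heterozygous SNPs (genotype `0/1` or `0|1`) on
#' non-excluded chromosomes, present in dbSNP, with total read depth
#' `ref_count + alt_count >= min_depth` and both per-allele counts
#' `>= min_allele_count`. Depth is defined as the sum of the two allelic
#' counts (the same x and n the binomial test uses), not an aligner total.
#'
#' Each rejected SNP is charged to the **first** failing rule in the fixed
#' order genotype -> chromosome -> dbSNP -> depth -> allele count, so the
#' report's rejection counts plus `n_pass` always account for every input
#' row. Chromosome matching accepts both `"chrX"` and `"X"` dialects, and
#' decoy/patch contigs (names containing `"_"` or `"decoy"`) are excluded
#' alongside the listed chromosomes.
#'
#' @param counts data.frame of allelic counts (see [read_counts()]).
#' @param min_depth minimum total depth (default 20).
#' @param min_allele_count minimum reads supporting each allele (default 2).
#' @param require_dbsnp drop SNPs with `in_dbsnp == FALSE` (default `TRUE`).
#' @param excluded_chromosomes chromosomes removed outright (default X, Y,
#'   mitochondrial).
#' @return list with `counts` (the retained rows, input order preserved) and
#'   `report`, an `asoc_filter_report` with fields `n_input`, `n_pass`, and
#'   per-rule rejection counts.
#' @examples
#' sim <- simulate_allelic_counts(sim_config(n_snps = 50, seed = 1))
#' apply_qualification_filters(sim$counts)$report
#' @export
apply_qualification_filters <- function(counts,
                                        min_depth = 20,
                                        min_allele_count = 2,
                                        require_dbsnp = TRUE,
                                        excluded_chromosomes = c("X", "Y",
                                                                 "MT")) {
  if (min_depth < 0 || min_allele_count < 0) {
    stop("thresholds must be non-negative", call. = FALSE)
  }
  n <- nrow(counts)
  depth <- counts$ref_count + counts$alt_count
  fail_gt <- !(counts$genotype %in% c("0/1", "0|1"))
  fail_chrom <- norm_chrom(counts$chrom) %in% norm_chrom(excluded_chromosomes) |
    is_decoy_chrom(counts$chrom)
  fail_dbsnp <- if (require_dbsnp) !counts$in_dbsnp else rep(FALSE, n)
  fail_depth <- depth < min_depth
  fail_allele <- pmin(counts$ref_count, counts$alt_count) < min_allele_count

  # charge each row to its first failing rule
  rule <- rep("pass", n)
  rule[fail_allele] <- "min_allele_count"
  rule[fail_depth] <- "depth"
  rule[fail_dbsnp] <- "dbsnp"
  rule[fail_chrom] <- "excluded_chromosome"
  rule[fail_gt] <- "non_heterozygous"

  keep <- rule == "pass"
  rules <- c("non_heterozygous", "excluded_chromosome", "dbsnp", "depth",
             "min_allele_count")
  rejections <- vapply(rules, function(r) sum(rule == r), integer(1))
  report <- structure(
    list(n_input = n, n_pass = sum(keep), rejections = rejections,
         params = list(min_depth = min_depth,
                       min_allele_count = min_allele_count,
                       require_dbsnp = require_dbsnp,
                       excluded_chromosomes = excluded_chromosomes)),
    class = "asoc_filter_report")
  list(counts = counts[keep, , drop = FALSE], report = report)
}

#' @export
print.asoc_filter_report <- function(x, ...) {
  cat("SNP qualification filter report\n")
  cat(sprintf("  input SNPs : %d\n", x$n_input))
  cat(sprintf("  retained   : %d\n", x$n_pass))
  for (r in names(x$rejections)) {
    cat(sprintf("  rejected by %-20s: %d\n", r, x$rejections[[r]]))
  }
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report an `asoc_filter_report`.
#' @return JSON string.
#' @export
filter_report_json <- function(report) {
  jsonlite::toJSON(list(n_input = report$n_input, n_pass = report$n_pass,
                        rejections = as.list(report$rejections)),
                   auto_unbox = TRUE, pretty = TRUE)
}
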
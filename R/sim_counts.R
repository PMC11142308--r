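# Synthetic allelic-count generator: heterozygous biallelic SNPs with
# beta-binomial counts, planted ASoC truth, optional reference bias and
# peak-aware placement.

#' Depth-model specifications
#'
#' Constructors for the per-SNP total read-depth model used by
#' [simulate_allelic_counts()].
#'
#' `depth_shifted_poisson(shift, lambda)` draws `depth = shift +
#' Poisson(lambda)`; the default `shift = 20` guarantees every simulated SNP
#' clears the DP >= 20 qualification filter, so filtering and power can be
#' probed independently. `depth_fixed(depth)` uses a constant depth.
#'
#' @param shift non-negative integer added to every draw.
#' @param lambda Poisson mean of the variable part.
#' @param depth constant total depth, >= 1.
#' @return a depth-model spec (list with a `family` field) accepted by
#'   [sim_config()].
#' @examples
#' depth_shifted_poisson(20, 40)
#' depth_fixed(200)
#' @export
depth_shifted_poisson <- function(shift = 20, lambda = 40) {
  if (!is.numeric(shift) || shift < 0 || !is.numeric(lambda) || lambda < 0) {
    stop("shift and lambda must be non-negative numbers", call. = FALSE)
  }
  structure(list(family = "shifted_poisson", shift = as.integer(shift),
                 lambda = lambda), class = "asoc_depth_model")
}

#' @rdname depth_shifted_poisson
#' @export
depth_fixed <- function(depth) {
  if (!is.numeric(depth) || depth < 1) stop("depth must be >= 1",
                                            call. = FALSE)
  structure(list(family = "fixed", depth = as.integer(depth)),
            class = "asoc_depth_model")
}

draw_depths <- function(model, n) {
  if (!inherits(model, "asoc_depth_model") || is.null(model$family)) {
    stop("invalid depth-model spec; use depth_shifted_poisson() or ",
         "depth_fixed()", call. = FALSE)
  }
  d <- switch(model$family,
    shifted_poisson = model$shift + rpois(n, model$lambda),
    fixed = rep.int(model$depth, n),
    stop("unknown depth-model family: ", model$family, call. = FALSE)
  )
  pmax(as.integer(d), 1L)  # all depths >= 1 by contract
}

#' Simulation configuration for allelic counts
#'
#' Bundles and validates the parameters of the allelic-count simulator.
#'
#' @param n_snps number of heterozygous SNPs to simulate.
#' @param depth_model depth-model spec from [depth_shifted_poisson()] or
#'   [depth_fixed()].
#' @param pi_asoc fraction of SNPs planted as true ASoC, in \[0, 1\].
#' @param theta_asoc true alternative-allele fraction for planted ASoC SNPs:
#'   a scalar in (0, 1) different from 0.5, or a vector of such values from
#'   which each ASoC SNP samples uniformly.
#' @param rho beta-binomial overdispersion in \[0, 1); `rho = 0` gives pure
#'   binomial counts. Shape parameters are `a = theta * (1 - rho) / rho`,
#'   `b = (1 - theta) * (1 - rho) / rho`, so the allelic-fraction variance at
#'   depth n is `theta * (1 - theta) * (1 + (n - 1) * rho) / n`.
#' @param ref_bias multiplicative capture bias toward the reference allele,
#'   > 0; 1 is unbiased. The effective alternative-allele fraction is
#'   `theta / (theta + (1 - theta) * ref_bias)`.
#' @param frac_in_peaks fraction of SNPs placed inside open-chromatin peaks
#'   when an annotation is supplied to [simulate_allelic_counts()].
#' @param seed integer RNG seed; identical (config, seed) gives
#'   byte-identical output.
#' @return an object of class `asoc_sim_config`.
#' @examples
#' sim_config(n_snps = 1000, pi_asoc = 0.1, theta_asoc = 0.75, seed = 7)
#' @export
sim_config <- function(n_snps = 1000,
                       depth_model = depth_shifted_poisson(),
                       pi_asoc = 0.1,
                       theta_asoc = 0.75,
                       rho = 0,
                       ref_bias = 1,
                       frac_in_peaks = 1,
                       seed = 1L) {
  if (!is.numeric(n_snps) || length(n_snps) != 1L || n_snps < 0) {
    stop("n_snps must be a single non-negative number", call. = FALSE)
  }
  stop_if_not_scalar_prob(pi_asoc, "pi_asoc")
  stop_if_not_scalar_prob(rho, "rho", open_right = TRUE)
  stop_if_not_scalar_prob(frac_in_peaks, "frac_in_peaks")
  if (!is.numeric(theta_asoc) || length(theta_asoc) < 1L ||
      any(theta_asoc <= 0) || any(theta_asoc > 1) ||
      any(theta_asoc == 0.5)) {
    stop("theta_asoc must lie in (0, 1] and differ from 0.5", call. = FALSE)
  }
  if (!is.numeric(ref_bias) || length(ref_bias) != 1L || ref_bias <= 0) {
    stop("ref_bias must be a single positive number", call. = FALSE)
  }
  structure(list(n_snps = as.integer(n_snps), depth_model = depth_model,
                 pi_asoc = pi_asoc, theta_asoc = theta_asoc, rho = rho,
                 ref_bias = ref_bias, frac_in_peaks = frac_in_peaks,
                 seed = as.integer(seed)),
            class = "asoc_sim_config")
}

# One beta-binomial draw per element; rho = 0 degenerates to binomial.
rbetabinom_vec <- function(depth, theta, rho) {
  n <- length(depth)
  if (rho == 0) return(rbinom(n, depth, theta))
  a <- theta * (1 - rho) / rho
  b <- (1 - theta) * (1 - rho) / rho
  p <- numeric(n)
  ok <- theta > 0 & theta < 1
  p[ok] <- rbeta(sum(ok), a[ok], b[ok])
  p[!ok] <- theta[!ok]  # degenerate fractions 0/1 bypass the beta draw
  rbinom(n, depth, p)
}

#' Simulate allelic read counts at heterozygous SNPs
#'
#' Generates a table of heterozygous biallelic SNPs with reference and
#' alternative read counts, plus an aligned ground-truth table. Null SNPs
#' have true alternative-allele fraction 0.5; a planted fraction `pi_asoc`
#' are true-ASoC SNPs with fraction `theta_asoc`. Counts are beta-binomial
#' with overdispersion `rho`, and a multiplicative reference bias shifts the
#' effective fraction of every SNP.
#'
#' When `annotation` (from [simulate_genome_annotation()]) is supplied, a
#' fraction `frac_in_peaks` of SNPs is placed uniformly inside peaks and the
#' remainder strictly outside; without it, SNPs are placed uniformly on a
#' single synthetic chromosome and `in_peak` is `NA`.
#'
#' @param config an [sim_config()] object.
#' @param annotation optional result of [simulate_genome_annotation()].
#' @return list with elements `counts` (data.frame: chrom, pos, snp_id, ref,
#'   alt, ref_count, alt_count, genotype, in_dbsnp) and `truth` (data.frame:
#'   snp_id, is_asoc, theta_true, in_peak), aligned row-for-row by `snp_id`.
#' @examples
#' sim <- simulate_allelic_counts(sim_config(n_snps = 100, seed = 1))
#' head(sim$counts)
#' mean(sim$truth$is_asoc)
#' @export
simulate_allelic_counts <- function(config, annotation = NULL) {
  if (!inherits(config, "asoc_sim_config")) {
    stop("config must come from sim_config()", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_snps
  bases <- c("A", "C", "G", "T")

  depth <- draw_depths(config$depth_model, n)
  is_asoc <- runif(n) < config$pi_asoc
  theta_true <- rep(0.5, n)
  if (any(is_asoc)) {
    theta_true[is_asoc] <- if (length(config$theta_asoc) == 1L) {
      config$theta_asoc
    } else {
      sample(config$theta_asoc, sum(is_asoc), replace = TRUE)
    }
  }
  # multiplicative reference bias: effective alt fraction
  theta_eff <- theta_true / (theta_true + (1 - theta_true) * config$ref_bias)
  alt_count <- rbetabinom_vec(depth, theta_eff, config$rho)
  ref_count <- depth - alt_count

  if (is.null(annotation)) {
    chrom <- rep("chr1", n)
    pos <- if (n > 0) sample.int(100000000L, n) else integer(0)
    in_peak <- rep(NA, n)
  } else {
    placed <- place_snps(n, config$frac_in_peaks, annotation)
    chrom <- placed$chrom
    pos <- placed$pos
    in_peak <- placed$in_peak
  }

  ref <- if (n > 0) sample(bases, n, replace = TRUE) else character(0)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "",
                USE.NAMES = FALSE)
  snp_id <- sprintf("rs%07d", seq_len(n))

  counts <- data.frame(chrom = chrom, pos = pos, snp_id = snp_id,
                       ref = ref, alt = alt,
                       ref_count = as.integer(ref_count),
                       alt_count = as.integer(alt_count),
                       genotype = rep("0/1", n),
                       in_dbsnp = rep(TRUE, n),
                       stringsAsFactors = FALSE)
  truth <- data.frame(snp_id = snp_id, is_asoc = is_asoc,
                      theta_true = theta_true, in_peak = in_peak,
                      stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

# Place n SNPs: round(frac * n) uniformly inside peaks, the rest outside all
# peaks (rejection sampling against the peak set).
place_snps <- function(n, frac_in_peaks, annotation) {
  peaks <- annotation$peaks
  if (n == 0L) {
    return(list(chrom = character(0), pos = integer(0), in_peak = logical(0)))
  }
  if (nrow(peaks) == 0L && frac_in_peaks > 0) {
    stop("annotation has no peaks but frac_in_peaks > 0", call. = FALSE)
  }
  n_in <- round(frac_in_peaks * n)
  n_out <- n - n_in
  chrom <- character(n); pos <- integer(n)
  if (n_in > 0) {
    idx <- sample.int(nrow(peaks), n_in, replace = TRUE)
    # 1-based positions inside half-open [start, end): start+1 .. end
    w <- peaks$end[idx] - peaks$start[idx]
    off <- floor(runif(n_in) * w)
    chrom[seq_len(n_in)] <- peaks$chrom[idx]
    pos[seq_len(n_in)] <- as.integer(peaks$start[idx] + 1L + off)
  }
  if (n_out > 0) {
    lens <- annotation$chrom_lengths
    pk_gr <- bed_to_granges(peaks)
    got <- 0L
    out_chrom <- character(n_out); out_pos <- integer(n_out)
    while (got < n_out) {
      m <- (n_out - got) * 2L
      ch <- sample(names(lens), m, replace = TRUE,
                   prob = lens / sum(lens))
      pp <- as.integer(floor(runif(m) * lens[ch]) + 1L)
      gr <- harmonize_seqlevels(points_to_granges(ch, pp), pk_gr)
      hit <- IRanges::overlapsAny(gr[[1]], gr[[2]])
      keep <- which(!hit)
      take <- utils::head(keep, n_out - got)
      if (length(take)) {
        out_chrom[got + seq_along(take)] <- ch[take]
        out_pos[got + seq_along(take)] <- pp[take]
        got <- got + length(take)
      }
    }
    chrom[n_in + seq_len(n_out)] <- out_chrom
    pos[n_in + seq_len(n_out)] <- out_pos
  }
  list(chrom = chrom, pos = pos,
       in_peak = rep(c(TRUE, FALSE), c(n_in, n_out)))
}
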
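#' Exact two-sided binomial test of allelic balance
#'
#' Computes the two-sided p-value for observing `ref_count` reference and
#' `alt_count` alternative reads at a heterozygous site under the null that
#' each read carries either allele with probability 0.5. The p-value is the
#' symmetric tail sum
#' \deqn{p = P(X \le k) + P(X \ge n - k), \quad k = \min(ref, alt),}
#' for \eqn{X \sim \mathrm{Binomial}(n, 0.5)}, clamped at 1. Because the
#' Binomial(n, 1/2) pmf is symmetric, this coincides with the
#' "sum all outcomes at least as extreme" convention used by
#' `binom.test(..., alternative = "two.sided")`; the tail sums are exact
#' (no normal approximation).
#'
#' @param ref_count,alt_count non-negative integer vectors of per-allele read
#'   counts (recycled to common length). `ref_count + alt_count` must be
#'   at least 1 for every element.
#' @return numeric vector of p-values in (0, 1]. Values are never exactly 0:
#'   the smallest attainable value at depth n is `2 * 0.5^n`, kept in full
#'   double precision for downstream -log transforms.
#' @examples
#' binomial_two_sided_p(10, 10)   # balanced: 1
#' binomial_two_sided_p(20, 0)    # 2 * 0.5^20
#' binomial_two_sided_p(15, 5)    # ~0.0414
#' @export
binomial_two_sided_p <- function(ref_count, alt_count) {
  n <- ref_count + alt_count
  if (length(n) == 0L) return(numeric(0))
  if (any(is.na(n)) || any(ref_count < 0) || any(alt_count < 0)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  if (any(n < 1)) stop("depth (ref_count + alt_count) must be >= 1",
                       call. = FALSE)
  k <- pmin(ref_count, alt_count)
  p <- pbinom(k, n, 0.5) + pbinom(n - k - 1, n, 0.5, lower.tail = FALSE)
  pmin(p, 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH step-up: with order statistics \eqn{p_{(1)} \le \dots \le
#' p_{(n)}}, the adjusted value is \eqn{q_{(i)} = \min_{j \ge i}
#' p_{(j)} n / j}, clamped at 1, returned in the original order. Ties share
#' the same adjusted value.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric vector of BH-adjusted values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.9))
#' @export
bh_adjust <- function(p) {
  n <- length(p)
  if (n == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / seq.int(n, 1L) * p[o]))
  q[ro]
}
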
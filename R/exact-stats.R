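#' Upper-tail hypergeometric probability
#'
#' Computes \eqn{P[X \ge x]} for \eqn{X \sim} Hypergeometric(N, K, n): the
#' probability of drawing at least `x` marked items when `n` items are drawn
#' without replacement from a universe of `N` items of which `K` are marked.
#' This is the overlap statistic used to score cross-species module pairs:
#' `N` orthogroups in the shared universe, `K` in one module, `n` in the
#' other, `x` in both.
#'
#' The tail is accumulated in log space (via `lchoose()`) so that very small
#' p-values for large, highly significant overlaps do not underflow term by
#' term.
#'
#' @param x Observed overlap (non-negative integer). Values above
#'   `min(K, n)` return 0 by convention (the event is impossible only in the
#'   sense that a larger overlap cannot be observed; the tail beyond the
#'   support is empty).
#' @param N Universe size.
#' @param K Number of marked items (first set size).
#' @param n Number of draws (second set size).
#' @return A single probability in \[0, 1\].
#' @examples
#' hypergeom_upper_tail(3, N = 10, K = 4, n = 5) # 66/252
#' hypergeom_upper_tail(0, N = 10, K = 4, n = 5) # 1
#' @seealso [fisher_two_sided()], [benjamini_hochberg()]
#' @export
hypergeom_upper_tail <- function(x, N, K, n) {
  stopifnot(length(x) == 1, length(N) == 1, length(K) == 1, length(n) == 1)
  vals <- c(x = x, N = N, K = K, n = n)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals))) {
    stop("hypergeom_upper_tail: arguments must be non-negative integers")
  }
  if (K > N || n > N) {
    stop("hypergeom_upper_tail: inconsistent margins (K and n must be <= N)")
  }
  hi <- min(K, n)
  if (x > hi) {
    return(0)
  }
  lo <- max(0L, n + K - N)
  i <- max(x, lo):hi
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  # log-sum-exp; the support below x contributes nothing
  m <- max(logp)
  p <- exp(m + log(sum(exp(logp - m))))
  min(p, 1)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table \eqn{(a, b; c, d)} with all margins
#' fixed, defined as the sum of probabilities of every table (under the
#' hypergeometric null) whose point probability does not exceed that of the
#' observed table. A relative tolerance of 1e-7 guards against floating-point
#' ties, matching the convention of standard statistical software.
#'
#' @param a,b,c,d Non-negative integer cell counts; `a` and `b` share the
#'   first row, `a` and `c` the first column.
#' @return A single p-value in (0, 1\]; an all-zero table returns 1.
#' @examples
#' fisher_two_sided(3, 1, 1, 3) # 34/70
#' fisher_two_sided(5, 0, 0, 5) # 2/252
#' @export
fisher_two_sided <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("fisher_two_sided: cell counts must be non-negative integers")
  }
  N <- a + b + c + d
  if (N == 0) {
    return(1)
  }
  K <- a + b # first-row margin
  n <- a + c # first-column margin
  lo <- max(0L, n + K - N)
  hi <- min(K, n)
  i <- lo:hi
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  obs <- logp[match(a, i)]
  keep <- logp <= obs + log1p(1e-7)
  m <- max(logp[keep])
  p <- exp(m + log(sum(exp(logp[keep] - m))))
  min(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment; a thin wrapper around
#' [stats::p.adjust()] with `method = "BH"`, kept as a named entry point so
#' that every enrichment table in the pipeline adjusts p-values the same way.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("benjamini_hochberg: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
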
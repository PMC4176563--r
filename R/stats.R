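# Exact small-sample rank tests.
#
# Exact two-sided p-values are computed by the shift algorithm: the
# permutation distribution of the (midrank) statistic is built as a
# generating-function convolution over doubled midranks (doubling keeps the
# support on integers in the presence of ties).  For sample sizes above the
# exact cutoff a normal approximation with tie and continuity corrections is
# used.

# distribution of the rank sum of all size-m subsets of the doubled
# midranks r2; returns counts indexed by 0..sum(r2)
.ranksum_counts <- function(r2, m) {
  maxs <- sum(r2)
  f <- matrix(0, m + 1L, maxs + 1L)
  f[1L, 1L] <- 1
  for (v in r2) {
    kmax <- min(m, nrow(f) - 1L)
    for (k in kmax:1L) {
      if (v + 1L <= maxs) {
        f[k + 1L, (v + 1L):(maxs + 1L)] <-
          f[k + 1L, (v + 1L):(maxs + 1L)] + f[k, 1L:(maxs + 1L - v)]
      } else {
        f[k + 1L, maxs + 1L] <- f[k + 1L, maxs + 1L] + f[k, 1L]
      }
    }
  }
  f[m + 1L, ]
}

#' Exact Mann-Whitney U test
#'
#' U is computed with midrank tie handling.  When n1 + n2 <=
#' \code{exact_max_n} the two-sided p-value is exact over all
#' choose(n1+n2, n1) group labelings (permutation null, deviation of U from
#' its mean n1*n2/2); otherwise a normal approximation with tie and
#' continuity correction is used.  Identical constant samples give p = 1.
#'
#' @param x,y numeric vectors, non-empty.
#' @param exact_max_n exact-enumeration cutoff on n1 + n2 (default 10).
#' @return list with \code{U}, \code{p.value}, \code{exact} (logical).
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 10L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  dev <- abs(U - mu)
  if (n <= exact_max_n) {
    r2 <- as.integer(round(2 * r))
    counts <- .ranksum_counts(r2, n1)
    s_vals <- (seq_along(counts) - 1L) / 2          # possible rank sums
    u_vals <- s_vals - n1 * (n1 + 1) / 2
    p <- sum(counts[abs(u_vals - mu) >= dev - 1e-9]) / choose(n, n1)
    return(list(U = U, p.value = p, exact = TRUE))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = U, p.value = 1, exact = FALSE))
  z <- (dev - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  list(U = U, p.value = p, exact = FALSE)
}

#' Exact Wilcoxon signed-rank test
#'
#' Zero differences are dropped (with a warning when all are zero, returning
#' p = 1).  W is the sum of midranks of the positive differences.  When the
#' number of non-zero differences is at most \code{exact_max_n} the
#' two-sided p-value is exact over all 2^n sign assignments; otherwise a
#' normal approximation with tie and continuity correction is used.
#'
#' @param x numeric vector of differences, or the first member of the pairs.
#' @param y optional second member; differences are x - y.
#' @param exact_max_n exact-enumeration cutoff (default 12).
#' @return list with \code{W}, \code{p.value}, \code{exact}, \code{n_used}.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max_n = 12L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(list(W = 0, p.value = 1, exact = TRUE, n_used = 0L))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  dev <- abs(W - mu)
  if (n <= exact_max_n) {
    r2 <- as.integer(round(2 * r))
    # subset-sum counts over all sign vectors: polynomial product of (1 + z^v)
    maxs <- sum(r2)
    g <- numeric(maxs + 1L); g[1L] <- 1
    for (v in r2) {
      g[(v + 1L):(maxs + 1L)] <- g[(v + 1L):(maxs + 1L)] + g[1L:(maxs + 1L - v)]
    }
    w_vals <- (seq_along(g) - 1L) / 2
    p <- sum(g[abs(w_vals - mu) >= dev - 1e-9]) / 2^n
    return(list(W = W, p.value = p, exact = TRUE, n_used = n))
  }
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(list(W = W, p.value = 1, exact = FALSE, n_used = n))
  z <- (dev - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  list(W = W, p.value = p, exact = FALSE, n_used = n)
}
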
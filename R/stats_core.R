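#' Upper-tail hypergeometric probability
#'
#' Computes \eqn{P(X \ge a)} for \eqn{X \sim} Hypergeometric with `K`
#' marked elements, `n` draws without replacement from a universe of `N`.
#' The tail is accumulated in log space from log-binomial coefficients so
#' the result stays finite and accurate for universes of millions of bins.
#'
#' @param a observed count of marked elements among the draws.
#' @param K number of marked elements in the universe.
#' @param n number of draws.
#' @param N universe size.
#' @return probability in `[0, 1]`.
#' @examples
#' hypergeom_sf(4, K = 4, n = 5, N = 10) # 6/252
#' @export
hypergeom_sf <- function(a, K, n, N) {
  if (N <= 0) ps_stop("universe size N must be positive")
  if (K > N || n > N) ps_stop("inconsistent margins: K and n must not exceed N")
  if (a < 0 || a > min(K, n)) ps_stop("a must lie in [0, min(K, n)]")
  hi <- min(K, n)
  lo <- max(0, n - (N - K))
  x <- max(a, lo):hi
  lt <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  min(1, exp(logsumexp(lt)))
}

#' Two-sample Mann-Whitney / Wilcoxon rank-sum test
#'
#' U statistic with midranks for ties. The p-value is exact (full
#' enumeration of rank assignments) when the smaller sample has at most
#' `exact_cutoff` observations and the pooled data are tie-free; otherwise
#' a normal approximation with tie-corrected variance and optional
#' continuity correction is used. Two-sided p-values double the smaller
#' one-sided tail and are capped at 1.
#'
#' @param x,y numeric samples.
#' @param alternative "two.sided", "less" or "greater" (for the location
#'   of `x` relative to `y`).
#' @param exact_cutoff largest min(n1, n2) for which the exact branch is
#'   attempted.
#' @param correct apply the 0.5 continuity correction in the normal branch.
#' @return an object of class `mw_test` with fields `statistic` (U for
#'   `x`), `p_value`, `method` ("mw_exact" or "mw_normal"), `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4)) # U = 0, exact p = 2/6
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         exact_cutoff = 8, correct = TRUE) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) ps_stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) ps_stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0

  if (!has_ties && min(n1, n2) <= exact_cutoff) {
    # exact null distribution of U by enumeration of all rank assignments
    combs <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(seq_len(n1 + n2)[combs], nrow = n1)) -
      n1 * (n1 + 1) / 2
    p_le <- mean(us <= u)
    p_ge <- mean(us >= u)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      less = p_le,
      greater = p_ge)
    method <- "mw_exact"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    ties <- table(pooled)
    tiecorr <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * (nn + 1 - tiecorr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      cc <- if (correct) 0.5 else 0
      z_g <- (u - mu - cc) / sqrt(sigma2) # for P(U >= u)
      z_l <- (u - mu + cc) / sqrt(sigma2) # for P(U <= u)
      p_ge <- stats::pnorm(z_g, lower.tail = FALSE)
      p_le <- stats::pnorm(z_l)
      p <- switch(alternative,
        two.sided = min(1, 2 * min(p_le, p_ge)),
        less = p_le,
        greater = p_ge)
    }
    method <- "mw_normal"
  }
  structure(
    list(statistic = u, p_value = p, method = method, n1 = n1, n2 = n2,
         continuity_correction = if (method == "mw_normal") correct else NA),
    class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat("Mann-Whitney rank-sum test (", x$method, ")\n", sep = "")
  cat(sprintf("  U = %g, n1 = %d, n2 = %d, p = %.4g\n",
              x$statistic, x$n1, x$n2, x$p_value))
  invisible(x)
}
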
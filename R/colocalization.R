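#' Count peak-wise overlaps between two peak sets
#'
#' An A peak "overlaps" when it shares at least one base pair with at
#' least one B peak; each A peak is counted at most once.
#'
#' @param A,B peak data.frames (0-based half-open intervals).
#' @return list with `n_overlapping_A` and `fraction_A`.
#' @export
count_peak_overlaps <- function(A, B) {
  if (!nrow(A)) ps_stop("peak set A is empty")
  if (!nrow(B)) return(list(n_overlapping_A = 0L, fraction_A = 0))
  hits <- GenomicRanges::countOverlaps(df_to_granges(A), df_to_granges(B))
  n <- sum(hits > 0)
  list(n_overlapping_A = n, fraction_A = n / nrow(A))
}

# bin indices (0-based) hit by a set of intervals on one chromosome
hit_bins <- function(start, end, bin_width, n_bins) {
  if (!length(start)) return(integer(0))
  idx <- unlist(mapply(function(s, e) seq.int(s %/% bin_width,
                                              min((e - 1) %/% bin_width,
                                                  n_bins - 1)),
                       start, end, SIMPLIFY = FALSE))
  unique(idx[idx >= 0])
}

#' Bin-level contingency table for two peak sets
#'
#' Tiles the genome into non-overlapping bins; a bin is "hit" by a set
#' when any peak of the set overlaps it. Returns the 2x2 table
#' `(a, b, c, d)` = (both, A-only, B-only, neither) over all `N` bins,
#' the universe on which the hypergeometric colocalization test runs.
#'
#' @param A,B peak data.frames.
#' @param genome named vector of chromosome lengths (bp).
#' @param bin_width bin size in bp; defaults to the median A peak width.
#' @return list with `a`, `b`, `c`, `d`, `N`, `bin_width`.
#' @export
binned_contingency <- function(A, B, genome, bin_width = NULL) {
  if (is.null(bin_width))
    bin_width <- round(stats::median(A$end - A$start))
  if (bin_width <= 0) ps_stop("bin_width must be positive")
  if (bin_width > min(genome))
    ps_stop("bin_width (", bin_width, ") exceeds the smallest chromosome")
  a <- b <- cc <- 0L; N <- 0L
  for (ch in names(genome)) {
    nb <- as.integer(ceiling(genome[[ch]] / bin_width))
    N <- N + nb
    ai <- with(A[A$chrom == ch, , drop = FALSE],
               hit_bins(start, end, bin_width, nb))
    bi <- with(B[B$chrom == ch, , drop = FALSE],
               hit_bins(start, end, bin_width, nb))
    both <- length(intersect(ai, bi))
    a <- a + both
    b <- b + length(ai) - both
    cc <- cc + length(bi) - both
  }
  list(a = a, b = b, c = cc, d = N - a - b - cc, N = N,
       bin_width = bin_width)
}

#' Hypergeometric overlap test on a 2x2 bin table
#'
#' Upper-tail hypergeometric probability of at least `a` co-hit bins when
#' the `a + b` A-hit bins are drawn without replacement from the `N`-bin
#' universe holding `a + c` B-hit bins, plus the odds ratio
#' `(a d)/(b c)`. When any cell is zero all four cells receive the
#' Haldane-Anscombe +0.5 correction before the odds ratio.
#'
#' @param a,b,c,d contingency cells (both, A-only, B-only, neither).
#' @return list with `p_value` and `odds_ratio`.
#' @export
hypergeometric_overlap_test <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) ps_stop("contingency cells must be non-negative")
  N <- a + b + c + d
  if (N == 0) ps_stop("empty contingency table")
  p <- hypergeom_sf(a, K = a + b, n = a + c, N = N)
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  list(p_value = p,
       odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]))
}

#' Colocalization test between two peak sets
#'
#' Combines peak-wise overlap counting, the binned contingency table and
#' the hypergeometric test into one result.
#'
#' @inheritParams binned_contingency
#' @return object of class `overlap_result` with fields
#'   `n_overlapping_A`, `fraction_A`, `contingency`, `p_value`,
#'   `odds_ratio`, `universe_bins`, `bin_width`.
#' @export
coloc_test <- function(A, B, genome, bin_width = NULL) {
  ov <- count_peak_overlaps(A, B)
  ct <- binned_contingency(A, B, genome, bin_width)
  ht <- hypergeometric_overlap_test(ct$a, ct$b, ct$c, ct$d)
  structure(list(
    n_overlapping_A = ov$n_overlapping_A, fraction_A = ov$fraction_A,
    contingency = c(a = ct$a, b = ct$b, c = ct$c, d = ct$d),
    p_value = ht$p_value, odds_ratio = ht$odds_ratio,
    universe_bins = ct$N, bin_width = ct$bin_width), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Peak colocalization\n")
  cat(sprintf("  %d A peaks overlap B (%.1f%%)\n", x$n_overlapping_A,
              100 * x$fraction_A))
  cat(sprintf("  bins (both/A/B/neither): %d/%d/%d/%d of N = %d (width %d bp)\n",
              x$contingency["a"], x$contingency["b"], x$contingency["c"],
              x$contingency["d"], x$universe_bins, x$bin_width))
  cat(sprintf("  hypergeometric p = %.3g, odds ratio = %.3g\n", x$p_value,
              x$odds_ratio))
  invisible(x)
}

#' Permutation null for peak-set overlap
#'
#' Places the B peaks uniformly at random on their own chromosomes,
#' preserving widths, and recomputes the number of A peaks overlapping B.
#' The empirical p-value is `(1 + #{perm >= observed}) / (n_perm + 1)`.
#' Serves as a model-free check on the hypergeometric approximation.
#'
#' @inheritParams binned_contingency
#' @param n_perm number of permutations (at least 100).
#' @param seed RNG seed.
#' @return list with `observed`, `p_value`, `perm_counts`.
#' @export
permutation_overlap_test <- function(A, B, genome, n_perm = 999, seed = 1) {
  if (n_perm < 100) ps_stop("n_perm must be at least 100")
  w <- B$end - B$start
  maxw <- tapply(w, B$chrom, max)
  for (ch in names(maxw))
    if (maxw[[ch]] > genome[[ch]])
      ps_stop("B peak wider than chromosome ", ch)
  obs <- count_peak_overlaps(A, B)$n_overlapping_A
  grA <- df_to_granges(A)
  chrom_len <- unname(genome[B$chrom])
  perm_counts <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    ns <- floor(stats::runif(nrow(B)) * (chrom_len - w + 1))
    Bp <- data.frame(chrom = B$chrom, start = ns, end = ns + w)
    sum(GenomicRanges::countOverlaps(grA, df_to_granges(Bp)) > 0)
  }, numeric(1)))
  list(observed = obs,
       p_value = (1 + sum(perm_counts >= obs)) / (n_perm + 1),
       perm_counts = perm_counts)
}
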
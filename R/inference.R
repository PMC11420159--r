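# Block-permutation (Pitman) tests, BH-FDR control, and the one-sided
# rank-sum comparison.
#
# The correlation null is built by cutting the second series into
# consecutive fixed-length blocks and permuting whole blocks only: this
# preserves within-block autocorrelation, so the surrogate distribution
# reflects the serial dependence of EEG rather than an i.i.d. fantasy.
# p-values use the add-one Monte-Carlo convention (1 + k) / (1 + N), which
# keeps p > 0. When the permutation space is small enough the null is
# enumerated exhaustively instead of sampled.

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) for (s in sub) {
    k <- k + 1L
    out[[k]] <- c(i, ifelse(s >= i, s + 1L, s))
  }
  out
}

#' Block-permutation test for a correlation
#'
#' Observed statistic: Pearson r between the two series (truncated to a
#' whole number of blocks). Null: the second series is cut into
#' consecutive `block_len_s` blocks whose order is permuted uniformly and
#' r recomputed. Two-sided p-value: proportion of permutations with
#' `|r_perm| >= |r_obs|` under the add-one convention. If `factorial(n
#' blocks) <= n_perm` the permutation space is enumerated exhaustively.
#'
#' @param a,b equal-length numeric series.
#' @param fs sampling rate in Hz.
#' @param block_len_s block length in seconds (default 10).
#' @param n_perm number of permutations (default 1600).
#' @param seed RNG seed for the permutation draw.
#' @param mask optional logical per block; `TRUE` blocks (artifacts) are
#'   dropped from the pool before permuting.
#' @param alpha significance level for the companion decision
#'   (default 0.01).
#' @return object of class `permutation_result`: list with
#'   `observed_stat`, `null_stats`, `p_two_sided`, `significant`,
#'   `n_perm` (effective), `exhaustive`, `block_len_s`, `n_blocks`, `seed`.
#' @export
permutation_corr_test <- function(a, b, fs, block_len_s = 10,
                                  n_perm = 1600, seed = 1, mask = NULL,
                                  alpha = 0.01) {
  n <- length(a)
  stopifnot(length(b) == n, fs > 0, block_len_s > 0, n_perm >= 1)
  bl <- round(block_len_s * fs)
  nb <- floor(n / bl)
  if (nb < 2L) stop("need at least 2 blocks for a permutation null")
  keep_blocks <- seq_len(nb)
  if (!is.null(mask)) {
    stopifnot(length(mask) == nb)
    keep_blocks <- which(!mask)
    if (length(keep_blocks) < 2L) stop("fewer than 2 clean blocks")
  }
  A <- matrix(a[seq_len(nb * bl)], nrow = bl)[, keep_blocks, drop = FALSE]
  B <- matrix(b[seq_len(nb * bl)], nrow = bl)[, keep_blocks, drop = FALSE]
  nb <- length(keep_blocks)
  N <- nb * bl
  Sa <- sum(A); Sb <- sum(B)
  ctr_a <- sum(A^2) - Sa^2 / N
  ctr_b <- sum(B^2) - Sb^2 / N
  if (ctr_a <= 0 || ctr_b <= 0) stop("zero-variance input")
  den <- sqrt(ctr_a * ctr_b)
  CP <- crossprod(A, B)                    # CP[i, j] = sum(A_i * B_j)
  r_from_S <- function(S) (S - Sa * Sb / N) / den
  r_obs <- r_from_S(sum(diag(CP)))
  exhaustive <- factorial(nb) <= n_perm
  perms <- if (exhaustive) {
    all_perms(nb)
  } else {
    set.seed(seed)
    replicate(n_perm, sample.int(nb), simplify = FALSE)
  }
  ii <- seq_len(nb)
  null_stats <- vapply(perms, function(p)
    r_from_S(sum(CP[cbind(ii, p)])), numeric(1))
  k <- sum(abs(null_stats) >= abs(r_obs) - 1e-12)
  p <- (1 + k) / (1 + length(perms))
  structure(list(observed_stat = r_obs, null_stats = null_stats,
                 p_two_sided = p, significant = p < alpha,
                 n_perm = length(perms), exhaustive = exhaustive,
                 block_len_s = block_len_s, n_blocks = nb, seed = seed),
            class = "permutation_result")
}

#' Permutation test for a difference of means
#'
#' Observed statistic: `mean(x) - mean(y)`. Null: group labels permuted
#' over the pooled values; two-sided add-one p-value on the absolute
#' difference. When `choose(nx + ny, nx) <= n_perm` all label assignments
#' are enumerated.
#'
#' @param x,y nonempty numeric vectors.
#' @param n_perm number of permutations (default 1600).
#' @param seed RNG seed.
#' @param alpha significance level for the companion decision
#'   (default 0.01).
#' @return a `permutation_result` (fields as in
#'   [permutation_corr_test()], with `n_blocks`/`block_len_s` absent).
#' @export
permutation_mean_diff_test <- function(x, y, n_perm = 1600, seed = 1,
                                       alpha = 0.01) {
  stopifnot(length(x) >= 1, length(y) >= 1, n_perm >= 1)
  pool <- c(x, y)
  nx <- length(x); ny <- length(y); n <- nx + ny
  d_obs <- mean(x) - mean(y)
  exhaustive <- is.finite(choose(n, nx)) && choose(n, nx) <= n_perm
  mean_pool <- mean(pool)
  diff_for <- function(idx) {
    mx <- mean(pool[idx])
    # mean of complement from the pooled total
    mx - (n * mean_pool - nx * mx) / ny
  }
  null_stats <- if (exhaustive) {
    apply(utils::combn(n, nx), 2L, diff_for)
  } else {
    set.seed(seed)
    replicate(n_perm, diff_for(sample.int(n, nx)))
  }
  k <- sum(abs(null_stats) >= abs(d_obs) - 1e-12)
  p <- (1 + k) / (1 + length(null_stats))
  structure(list(observed_stat = d_obs, null_stats = null_stats,
                 p_two_sided = p, significant = p < alpha,
                 n_perm = length(null_stats), exhaustive = exhaustive,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> stat = %.4f, p = %.4g (%s, %d perms)\n",
              x$observed_stat, x$p_two_sided,
              if (isTRUE(x$exhaustive)) "exhaustive" else "sampled",
              x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure at level `q`: with sorted p-values `p(1) <= ... <=
#' p(m)`, reject all hypotheses up to the largest `k` with
#' `p(k) <= k q / m`. Also returns BH-adjusted p-values
#' (via [stats::p.adjust()]); rejection is equivalent to
#' `adjusted <= q`.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `adjusted`, `reject` (logical), `q`. Empty input
#'   yields empty output.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1), q > 0, q < 1)
  if (length(pvals) == 0L)
    return(list(adjusted = numeric(0), reject = logical(0), q = q))
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q, q = q)
}

#' Right-tail Wilcoxon rank-sum test
#'
#' One-sided p-value for `x` stochastically larger than `y`: exact
#' enumeration for small untied samples, tie-corrected normal
#' approximation otherwise (the standard [stats::wilcox.test()]
#' behavior).
#'
#' @param x,y nonempty numeric vectors.
#' @return one-sided p-value.
#' @export
rank_sum_right <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater")$p.value)
}
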
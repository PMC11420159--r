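test_that("a perfectly correlated pair attains the add-one p-value floor", {
  fs <- 25
  set.seed(61)
  a <- rnorm(300 * fs)                      # 30 blocks of 10 s
  res <- permutation_corr_test(a, a, fs, n_perm = 400, seed = 9)
  expect_equal(res$observed_stat, 1)
  expect_equal(res$p_two_sided, 1 / 401)
  expect_true(res$significant)
  expect_length(res$null_stats, 400L)
  expect_error(permutation_corr_test(a[1:300], a[1:300], fs), "2 blocks")
})

test_that("3-block permutation p matches exhaustive enumeration under add-one", {
  fs <- 5
  set.seed(67)
  a <- rnorm(150); b <- 0.6 * a + rnorm(150)   # 3 blocks of 10 s
  res <- permutation_corr_test(a, b, fs, n_perm = 1600, seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 6L)
  expect_equal(res$p_two_sided, oracle_corr_p(a, b, fs, 10))
})

test_that("clean blocks only enter the permutation pool when a mask is supplied", {
  fs <- 25
  set.seed(71)
  a <- rnorm(100 * fs); b <- rnorm(100 * fs)
  mask <- c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  res <- permutation_corr_test(a, b, fs, n_perm = 100, seed = 2, mask = mask)
  expect_equal(res$n_blocks, 8L)
  expect_error(permutation_corr_test(a, b, fs, mask = c(rep(TRUE, 9), FALSE)),
               "fewer than 2")
})

test_that("mean-difference permutation handles identity, degenerate, and exact cases", {
  x <- c(3, 1, 4, 1, 5)
  same <- permutation_mean_diff_test(x, sample(x))
  expect_equal(same$observed_stat, 0)
  expect_equal(same$p_two_sided, 1)
  const <- permutation_mean_diff_test(rep(2, 4), rep(2, 6))
  expect_equal(const$p_two_sided, 1)
  res <- permutation_mean_diff_test(c(0, 0, 0, 0), c(10, 10, 10, 10),
                                    n_perm = 1600)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 70L)             # C(8, 4)
  expect_equal(res$p_two_sided,
               oracle_meandiff_p(c(0, 0, 0, 0), c(10, 10, 10, 10)))
  set.seed(73)
  for (i in 1:5) {
    x <- rnorm(4); y <- rnorm(3, mean = runif(1, 0, 2))
    expect_equal(permutation_mean_diff_test(x, y, n_perm = 200)$p_two_sided,
                 oracle_meandiff_p(x, y))
  }
})

test_that("permutation p-values are invariant to affine transforms of the inputs", {
  fs <- 25
  set.seed(79)
  a <- rnorm(120 * fs); b <- 0.3 * a + rnorm(120 * fs)
  p1 <- permutation_corr_test(a, b, fs, n_perm = 200, seed = 5)$p_two_sided
  p2 <- permutation_corr_test(5 * a - 2, -3 * b + 1, fs, n_perm = 200,
                              seed = 5)$p_two_sided
  expect_equal(p1, p2)
})

test_that("power rises with the shared-source correlation", {
  fs <- 25
  n <- 300 * fs
  ps <- vapply(c(0, 0.2, 0.4, 0.6), function(rho) {
    mean(vapply(1:3, function(seed) {
      set.seed(100 + seed)
      z <- rnorm(n)
      a <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(n)
      b <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(n)
      permutation_corr_test(a, b, fs, n_perm = 200, seed = seed)$p_two_sided
    }, numeric(1)))
  }, numeric(1))
  expect_lt(ps[3], 0.01)                     # rho = 0.4 detected
  expect_lt(ps[4], 0.01)
  expect_gt(ps[1], 0.05)                     # null not rejected on average
})

test_that("BH-FDR matches its examples and the step-up oracle, and is monotone", {
  r <- bh_fdr(c(0.002, 0.01, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))                 # largest k is 4
  expect_false(any(bh_fdr(rep(1, 6), q = 0.05)$reject))
  expect_true(bh_fdr(0.04, q = 0.05)$reject)
  expect_identical(bh_fdr(numeric(0))$reject, logical(0))
  set.seed(83)
  for (i in 1:30) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    r <- bh_fdr(p, q = 0.05)
    expect_identical(r$reject, oracle_bh_reject(p, 0.05))
    # monotone: rejecting p_i implies rejecting every p_j <= p_i
    if (any(r$reject)) expect_true(all(r$reject[p <= max(p[r$reject])]))
  }
})

test_that("the right-tail rank-sum p matches exact enumeration and is >= 0.5 under ties", {
  # oracle: enumerate all C(6,3) rank assignments of {4,5,6} vs {1,2,3}
  vals <- c(4, 5, 6, 1, 2, 3)
  w_obs <- sum(rank(vals)[1:3]) - 3 * 4 / 2   # Wilcoxon W for group 1
  ws <- apply(utils::combn(6, 3), 2L, function(idx)
    sum(rank(vals)[idx]) - 6)
  p_oracle <- mean(ws >= w_obs)
  expect_equal(rank_sum_right(c(4, 5, 6), c(1, 2, 3)), p_oracle)
  expect_gte(rank_sum_right(rep(1, 5), rep(1, 5)), 0.5)
  # agreement with the exact reference on random untied small samples
  set.seed(89)
  for (i in 1:50) {
    x <- runif(sample(3:5, 1)); y <- runif(sample(3:5, 1))
    nx <- length(x); n <- nx + length(y)
    pooled <- c(x, y)
    w_obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
    ws <- apply(utils::combn(n, nx), 2L, function(idx)
      sum(rank(pooled)[idx]) - nx * (nx + 1) / 2)
    expect_lt(abs(rank_sum_right(x, y) - mean(ws >= w_obs)), 1e-6)
  }
})
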
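test_that("contralateral montage pairs homologs and skips midline/unpaired electrodes", {
  m <- contralateral_montage(c("T7", "T8", "FT11", "FT12", "Cz", "Fz",
                               "Pz", "P1", "O1", "O2"))
  expect_true(all(c("T7-T8", "FT11-FT12", "O1-O2") %in% m$name))
  skipped <- attr(m, "skipped")
  expect_true(all(c("Cz", "Fz", "Pz", "P1") %in% skipped))
  expect_false(any(grepl("z", m$name)))
  expect_error(contralateral_montage(c("Cz", "Fz", "Pz")), "no pairable")
})

test_that("lag-tolerant cross-correlation recovers identity, delays, and independence", {
  fs <- 250
  set.seed(41)
  a <- bandpass_fir(rnorm(40 * fs), 2, 30, fs = fs)
  xc <- xcorr_max(a, a, fs)
  expect_equal(xc$r, 1)
  expect_equal(xc$best_lag_s, 0)
  # b delayed by 12 samples (48 ms) -> best lag recovered exactly, r ~ 1
  d <- 12L
  b <- c(rep(0, d), a[seq_len(length(a) - d)])
  keep <- (5 * fs):(35 * fs)
  xc2 <- xcorr_max(a[keep], b[keep], fs, max_lag_s = 0.1)
  expect_equal(xc2$best_lag_s, d / fs)
  expect_gt(xc2$r, 0.99)
  for (seed in 1:3) {
    set.seed(seed)
    expect_lt(abs(xcorr_max(rnorm(2500), rnorm(2500), fs)$r), 0.1)
  }
  expect_error(xcorr_max(rep(1, 100), rnorm(100), fs), "zero-variance")
})

test_that("cross-correlation is symmetric up to lag sign and affine-invariant", {
  fs <- 250
  set.seed(43)
  a <- rnorm(3000); b <- 0.5 * a + rnorm(3000)
  ab <- xcorr_max(a, b, fs); ba <- xcorr_max(b, a, fs)
  expect_equal(ab$r, ba$r, tolerance = 1e-12)
  expect_equal(ab$best_lag_s, -ba$best_lag_s)
  af <- xcorr_max(3 * a + 7, b, fs)
  expect_equal(af$r, ab$r, tolerance = 1e-12)
  expect_equal(af$best_lag_s, ab$best_lag_s)
})

test_that("the correlation map has one row per derivation with bounded r", {
  fs <- 250
  set.seed(47)
  src <- bandpass_fir(rnorm(60 * fs), 8, 12, fs = fs)
  derivs <- cbind("T7-T8" = src + rnorm(60 * fs, sd = 2),
                  "F7-F8" = rnorm(60 * fs),
                  "O1-O2" = rnorm(60 * fs))
  cmap <- alpha_correlation_map(src, derivs, fs)
  expect_equal(nrow(cmap), 3L)
  expect_true(all(abs(cmap$r) <= 1))
  expect_identical(cmap$derivation[which.max(abs(cmap$r))], "T7-T8")
  expect_error(alpha_correlation_map(src, derivs, fs,
                                     mask = rep(TRUE, 6)), "no clean")
})

test_that("agreement categories cover [0,1] with the conventional boundaries", {
  expect_identical(as.character(classify_agreement(0.3)), "fair")
  expect_identical(as.character(classify_agreement(0.62)), "substantial")
  expect_identical(as.character(classify_agreement(0.85)), "almost perfect")
  expect_identical(as.character(classify_agreement(-0.45)), "moderate")
  grid <- seq(0, 1, by = 0.01)
  cats <- classify_agreement(grid)
  expect_false(any(is.na(cats)))
  expect_identical(levels(cats),
                   c("poor", "fair", "moderate", "substantial",
                     "almost perfect"))
  expect_true(all(diff(as.integer(cats)) >= 0))   # monotone in |r|
})

test_that("amplitude-ratio slope matches exact proportionality and inverts under swap", {
  set.seed(53)
  p_in <- runif(20, 1, 50)
  p_sc <- 4 * p_in           # amplitude ratio 2 <-> power ratio 4
  fit <- amplitude_ratio(p_sc, p_in)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  swap <- amplitude_ratio(p_in, p_sc)
  expect_equal(swap$slope, 0.5, tolerance = 1e-12)
  expect_error(amplitude_ratio(c(1, 2), c(1, 2)), "at least 3")
  expect_error(amplitude_ratio(rep(4, 5), rep(1, 5)), "zero-variance")
})

test_that("stage correlations group windows by hypnogram stage and honor the mask", {
  fs <- 250
  set.seed(59)
  n_ep <- 6                                  # 3 min, 18 windows
  shared <- rnorm(n_ep * 30 * fs)
  a <- shared + rnorm(length(shared))
  b <- shared + rnorm(length(shared))
  hyp_wake <- hypnogram(rep("Wake", n_ep))
  sc <- stage_correlations(a, b, hyp_wake, fs)
  expect_equal(nrow(sc), 1L)
  expect_identical(sc$stage, "Wake")
  expect_equal(sc$n_windows, 18L)
  # flagging 20% of windows reduces the count accordingly (counting oracle)
  mask <- rep(FALSE, 18); mask[c(2, 5, 9, 13)] <- TRUE
  sc2 <- stage_correlations(a, b, hyp_wake, fs, mask = mask)
  expect_equal(sc2$n_windows, 14L)
  # stages absent from the hypnogram are absent from the output
  hyp_mix <- hypnogram(c("Wake", "Wake", "N2", "N2", "N3", "N3"))
  sc3 <- stage_correlations(a, b, hyp_mix, fs)
  expect_setequal(sc3$stage, c("Wake", "N2", "N3"))
})
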
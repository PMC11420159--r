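# independent statistical oracles used by the inference and acceptance tests

# all permutations of 1..n as a matrix (tiny n only)
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- perm_matrix(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, ifelse(sub >= i, sub + 1L, sub)))
  }
  out
}

# exhaustive block-permutation p for the correlation statistic
oracle_corr_p <- function(a, b, fs, block_len_s) {
  bl <- round(block_len_s * fs)
  nb <- floor(length(a) / bl)
  A <- matrix(a[seq_len(nb * bl)], nrow = bl)
  B <- matrix(b[seq_len(nb * bl)], nrow = bl)
  r_obs <- cor(as.vector(A), as.vector(B))
  rs <- apply(perm_matrix(nb), 1L, function(p)
    cor(as.vector(A), as.vector(B[, p])))
  (1 + sum(abs(rs) >= abs(r_obs) - 1e-12)) / (1 + length(rs))
}

# exhaustive label-permutation p for the mean difference
oracle_meandiff_p <- function(x, y) {
  pool <- c(x, y); nx <- length(x); n <- length(pool)
  d_obs <- mean(x) - mean(y)
  ds <- apply(utils::combn(n, nx), 2L, function(idx)
    mean(pool[idx]) - mean(pool[-idx]))
  (1 + sum(abs(ds) >= abs(d_obs) - 1e-12)) / (1 + length(ds))
}

# brute-force BH step-up: reject up to the largest k with p_(k) <= k q / m
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ks) > 0) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}

# per-epoch alpha power pairs, computed the way the pipeline does but from
# first principles (align -> resample -> broadband filter -> periodogram)
epoch_alpha_powers <- function(cfg) {
  sim <- generate_alpha_test(cfg)
  al <- align_pair(sim$scalp, sim$inear)
  sc <- resample_recording(sim$scalp, 250)
  cr <- earqc:::crop_to_grid(sc, al$recB_aligned)
  fs <- 250
  deriv <- get_channel(cr[[1]], "T7") - get_channel(cr[[1]], "T8")
  inear <- get_channel(cr[[2]], 1)
  in_bb <- bandpass_fir(inear, 0.3, 35, fs = fs)
  sc_bb <- bandpass_fir(deriv, 0.3, 35, fs = fs)
  spw <- 10 * fs
  nw <- floor(length(in_bb) / spw)
  trial <- floor((attr(cr, "t0") + (seq_len(nw) - 1) * 10) / 30) + 1
  ec <- which(trial %% 2 == 1 & trial <= cfg$n_trials)
  ap <- function(seg) {
    ps <- earqc:::window_psd(seg, fs)
    sum(ps[ps[, 1] >= 8 & ps[, 1] < 12, 2])
  }
  list(inear = vapply(ec, function(w)
         ap(in_bb[((w - 1) * spw + 1):(w * spw)]), numeric(1)),
       scalp = vapply(ec, function(w)
         ap(sc_bb[((w - 1) * spw + 1):(w * spw)]), numeric(1)))
}
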
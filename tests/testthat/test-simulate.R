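test_that("alpha session has exact duration, even-trial schedule, and is deterministic", {
  cfg <- quick_alpha_cfg(seed = 1)
  sim <- generate_alpha_test(cfg)
  expect_equal(n_samples(sim$inear), 300L * 250L)
  expect_equal(n_samples(sim$scalp), 300L * 2000L)
  # schedule conservation: EC + EO intervals tile the session exactly
  expect_equal(sum(sim$schedule$end_s - sim$schedule$start_s), 300)
  expect_identical(sim$schedule$condition[1], "EC")
  expect_identical(unique(diff(sim$schedule$start_s)), 30)
  # fixed-seed determinism, bit for bit
  sim2 <- generate_alpha_test(quick_alpha_cfg(seed = 1))
  expect_identical(sim$inear$data, sim2$inear$data)
  expect_identical(sim$scalp$data, sim2$scalp$data)
  expect_identical(sim$inear$trigger, sim2$inear$trigger)
  # invalid configurations are refused
  expect_error(sim_config("alpha_test", n_trials = 9), "even trial count")
  expect_error(sim_config("alpha_test", session_len_s = 299),
               "configuration error")
  expect_error(generate_nap(cfg), "protocol")
})

test_that("eyes-closed segments carry alpha power that eyes-open segments lack", {
  sim <- generate_alpha_test(quick_alpha_cfg(seed = 2))
  x <- get_channel(sim$inear, 1)
  fs <- 250
  ec <- unlist(lapply(which(sim$schedule$condition == "EC"), function(i)
    (sim$schedule$start_s[i] * fs + 1):(sim$schedule$end_s[i] * fs)))
  eo <- unlist(lapply(which(sim$schedule$condition == "EO"), function(i)
    (sim$schedule$start_s[i] * fs + 1):(sim$schedule$end_s[i] * fs)))
  ratio <- oracle_band_power(x[ec], fs, 8, 12) /
    oracle_band_power(x[eo], fs, 8, 12)
  expect_gt(ratio, 1)   # in practice it is >> 1; the contract is the direction
})

test_that("nap hypnogram length and per-stage spectral fidelity hold", {
  cfg <- sim_config("nap", nap_len_s = 900, scalp_channels = c("T7", "T8"),
                    artifact_rate = 0, clock_offset_s = 0,
                    clock_drift_ppm = 0, seed = 3)
  sim <- generate_nap(cfg)
  expect_equal(nrow(sim$hypnogram), 30L)       # floor(900 / 30)
  expect_setequal(as.character(unique(sim$hypnogram$stage)),
                  c("Wake", "N1", "N2", "N3", "REM"))
  # the template's loudest band dominates the generated segment (oracle)
  x <- get_channel(sim$inear, 1)
  fs <- 250
  edges <- list(delta = c(0.5, 2), theta = c(4, 7), alpha = c(8, 12),
                spindle = c(12, 16))
  tpl <- cfg$stage_template
  for (st in c("Wake", "N1", "N2", "N3")) {
    eps <- which(as.character(sim$hypnogram$stage) == st)
    idx <- unlist(lapply(eps, function(e) (e - 1L) * 30L * fs + seq_len(30L * fs)))
    bp <- vapply(edges, function(e) oracle_band_power(x[idx], fs, e[1], e[2]),
                 numeric(1))
    expect_identical(names(which.max(bp)), names(which.max(tpl[[st]])),
                     label = sprintf("dominant band in stage %s", st))
  }
  # N3 has the largest delta-band relative power among the stages
  rel_delta <- vapply(c("Wake", "N2", "N3"), function(st) {
    eps <- which(as.character(sim$hypnogram$stage) == st)
    idx <- unlist(lapply(eps, function(e) (e - 1L) * 30L * fs + seq_len(30L * fs)))
    oracle_band_power(x[idx], fs, 0.5, 2) / oracle_band_power(x[idx], fs, 0.3, 35)
  }, numeric(1))
  expect_identical(names(which.max(rel_delta)), "N3")
  # unknown stage in the template is a configuration error
  cfg_bad <- cfg
  cfg_bad$stage_template <- cfg$stage_template[c("Wake", "N1")]
  expect_error(generate_nap(cfg_bad), "stage_template")
})

test_that("scalp alpha envelope scales by amp_ratio against the in-ear channel in Wake", {
  cfg <- sim_config("nap", nap_len_s = 600, scalp_channels = c("T7", "T8"),
                    artifact_rate = 0, clock_offset_s = 0,
                    clock_drift_ppm = 0, seed = 4)
  sim <- generate_nap(cfg)
  fs <- 250
  sc <- resample_recording(sim$scalp, fs)
  deriv <- get_channel(sc, "T7") - get_channel(sc, "T8")
  x <- get_channel(sim$inear, 1)
  eps <- which(as.character(sim$hypnogram$stage) == "Wake")
  idx <- unlist(lapply(eps, function(e) (e - 1L) * 30L * fs + seq_len(30L * fs)))
  idx <- idx[idx <= min(length(deriv), length(x))]
  ratio <- sqrt(oracle_band_power(deriv[idx], fs, 8, 12) /
                  oracle_band_power(x[idx], fs, 8, 12))
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.6)
})

test_that("artifact injection is a no-op at zero rates and injects >100 uV excursions otherwise", {
  cfg <- quick_alpha_cfg(seed = 5)
  sim <- generate_alpha_test(cfg)
  clean <- inject_artifacts(sim$inear, cfg)   # artifact_rate = 0 in helper cfg
  expect_identical(clean$rec$data, sim$inear$data)
  expect_equal(nrow(clean$truth), 0L)

  cfg2 <- sim_config("alpha_test", scalp_channels = c("T7", "T8"),
                     artifact_rate = 2, contact_loss_prob = 0.05, seed = 5)
  sim2 <- generate_alpha_test(cfg2)
  inj <- inject_artifacts(sim2$inear, cfg2)
  expect_gt(nrow(inj$truth), 0L)
  excess <- abs(get_channel(inj$rec, 1) - get_channel(sim2$inear, 1))
  fs <- 250
  for (i in seq_len(nrow(inj$truth))) {
    w <- max(1, round(inj$truth$start_s[i] * fs)):
      min(length(excess), round(inj$truth$end_s[i] * fs))
    expect_gt(max(excess[w]), 100)
  }
  # deterministic under the same config
  inj2 <- inject_artifacts(sim2$inear, cfg2)
  expect_identical(inj$rec$data, inj2$rec$data)
})

test_that("flagged-epoch fraction matches the configured contact-loss contamination", {
  flagged <- 0L; total <- 0L
  p <- 0.1
  for (seed in 1:6) {
    cfg <- sim_config("alpha_test", n_trials = 40,
                      scalp_channels = c("T7", "T8"), artifact_rate = 0,
                      contact_loss_prob = p, seed = seed)
    sim <- generate_alpha_test(cfg)
    inj <- inject_artifacts(sim$inear, cfg)
    grid <- epoch_and_flag(inj$rec, 1L)
    # the flag set recovers the injected contamination exactly: every
    # contact-loss epoch trips the 10%-of-samples rule, no clean epoch does
    injected <- sort(unique(inj$truth$start_s[inj$truth$type ==
                                                "contact_loss"] / 10 + 1))
    expect_identical(which(grid$artifact_flag), as.integer(injected))
    flagged <- flagged + sum(grid$artifact_flag)
    total <- total + length(grid$artifact_flag)
  }
  # pooled count within the 99% binomial envelope around the configured rate
  expect_gte(flagged, qbinom(0.005, total, p))
  expect_lte(flagged, qbinom(0.995, total, p))
})

test_that("simulation round-trips through plain-text files", {
  cfg <- quick_alpha_cfg(seed = 6, n_trials = 2)
  sim <- generate_alpha_test(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- read_recording_csv(file.path(dir, "inear.csv"))
  expect_equal(back$fs, 250)
  expect_equal(back$data, sim$inear$data, tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$clock_offset_s, cfg$clock_offset_s)
})
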
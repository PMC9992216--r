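test_that("default profile set covers all 15 gestures, deterministically", {
  p <- default_profiles(seed = 0)
  expect_setequal(names(p), gesture_codes())
  expect_length(p, 15)
  for (prof in p) {
    expect_length(prof$channel_gains, 8)
    expect_true(all(prof$channel_gains >= 0))
    expect_gt(sum(prof$channel_gains), 0)
  }
  # pairwise distinct gain vectors
  gains <- sapply(p, function(x) x$channel_gains)
  expect_equal(nrow(unique(t(gains))), 15)
  expect_identical(default_profiles(seed = 0), p)
  p1 <- default_profiles(seed = 1)
  expect_false(all(sapply(gesture_codes(),
                          function(cc) isTRUE(all.equal(p[[cc]]$channel_gains,
                                                        p1[[cc]]$channel_gains)))))
})

test_that("gesture_profile validates its invariants", {
  expect_error(gesture_profile("T", rep(1, 7)), "8")
  expect_error(gesture_profile("T", c(rep(1, 7), -1)), "non-negative")
  expect_error(gesture_profile("T", rep(0, 8)), "positive")
})

test_that("sim_config rejects inconsistent protocols", {
  expect_error(sim_config(fs = 800), "fs")             # fs <= 2*450
  expect_error(sim_config(duration_s = 0), "duration")
  expect_error(sim_config(n_trials = 0), "n_trials")
  expect_error(sim_config(drift_strength = -1), "drift")
  expect_error(sim_config(band = c(450, 20)), "band")
})

test_that("a recording has fs * duration samples and is reproducible", {
  cfg <- sim_config(fs = 1000, duration_s = 2, drift_strength = 0, seed = 7)
  prof <- default_profiles(7)[["TI"]]
  r1 <- generate_recording(prof, cfg, subject_id = 2, trial_index = 3)
  expect_equal(dim(r1$data), c(8, 2000))
  expect_identical(r1$class_code, "TI")
  r2 <- generate_recording(prof, cfg, subject_id = 2, trial_index = 3)
  expect_identical(r1$data, r2$data)
  # different trial -> different stream
  r3 <- generate_recording(prof, cfg, subject_id = 2, trial_index = 1)
  expect_false(identical(r1$data, r3$data))
})

test_that("generated channels keep >= 90% of their power in 20-450 Hz", {
  cfg <- sim_config(fs = 4000, duration_s = 2, drift_strength = 0, seed = 5)
  r <- generate_recording(default_profiles(5)[["HC"]], cfg)
  for (ch in c(1, 4, 8)) {
    sp <- stats::spec.pgram(stats::ts(r$data[ch, ], frequency = cfg$fs),
                            plot = FALSE, taper = 0)
    frac <- sum(sp$spec[sp$freq >= 20 & sp$freq <= 450]) / sum(sp$spec)
    expect_gt(frac, 0.90)
  }
})

test_that("drift raises late-recording amplitude; no drift does not", {
  prof <- default_profiles(1)[["IM"]]
  for (ds in c(0, 1)) {
    cfg <- sim_config(fs = 1000, duration_s = 10, drift_strength = ds, seed = 9)
    r <- generate_recording(prof, cfg)
    n <- ncol(r$data)
    first <- mean(abs(r$data[, 1:(n %/% 10)]))
    last <- mean(abs(r$data[, (n - n %/% 10):n]))
    if (ds > 0) expect_gt(last / first, 1.1)
    else expect_lt(abs(last / first - 1), 0.1)
  }
})

test_that("generate_dataset is a complete, reproducible factorial", {
  cfg <- sim_config(n_subjects = 2, n_trials = 2, fs = 1000, duration_s = 1,
                    seed = 4)
  d <- generate_dataset(cfg)
  expect_length(d, 2 * 15 * 2)
  key <- sapply(d, function(r) paste(r$subject_id, r$class_code, r$trial_index))
  expect_equal(anyDuplicated(key), 0)
  # label fidelity: each recording regenerates identically in isolation
  profs <- default_profiles(cfg$seed)
  r <- d[[17]]
  r_iso <- generate_recording(profs[[r$class_code]], cfg, r$subject_id,
                              r$trial_index)
  expect_identical(r$data, r_iso$data)
  cfg1 <- sim_config(n_subjects = 1, n_trials = 1, fs = 1000, duration_s = 1)
  expect_length(generate_dataset(cfg1), 15)
})

test_that("two orthogonal-gain classes decode near-perfectly at high SNR", {
  p1 <- gesture_profile("T", c(1, 1, 1, 1, 0, 0, 0, 0))
  p2 <- gesture_profile("L", c(0, 0, 0, 0, 1, 1, 1, 1))
  cfg <- sim_config(fs = 1000, duration_s = 5, snr_db = 30,
                    drift_strength = 0, seed = 1)
  recs <- unlist(lapply(list(p1, p2), function(p)
    lapply(1:3, function(tr) generate_recording(p, cfg, 1, tr))),
    recursive = FALSE)
  res <- within_srd_eval(recs, 5, "NTDF", classifier_spec("LDA"))[[1]]
  expect_gt(res$ca, 95)
})

test_that("raising SNR never hurts downstream accuracy (separability dial)", {
  p1 <- gesture_profile("T", c(1, 1, 1, 1, 0, 0, 0, 0))
  p2 <- gesture_profile("I", c(0, 0, 1, 1, 1, 1, 0, 0))
  ca_at <- function(snr, seed) {
    cfg <- sim_config(fs = 1000, duration_s = 3, snr_db = snr,
                      drift_strength = 0, seed = seed)
    recs <- unlist(lapply(list(p1, p2), function(p)
      lapply(1:3, function(tr) generate_recording(p, cfg, 1, tr))),
      recursive = FALSE)
    within_srd_eval(recs, 3, "NTDF", classifier_spec("LDA"))[[1]]$ca
  }
  for (snrs in list(c(-10, 0), c(0, 15))) {
    lo <- mean(sapply(1:3, function(s) ca_at(snrs[1], s)))
    hi <- mean(sapply(1:3, function(s) ca_at(snrs[2], s)))
    expect_gte(hi, lo - 1)  # 1% tolerance
  }
})
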
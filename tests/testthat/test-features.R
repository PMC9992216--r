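test_that("feature operators reproduce hand-computed examples", {
  expect_equal(mav(c(1, -1, 2, -2)), 1.5)
  expect_equal(mav(rep(0, 5)), 0)
  expect_equal(wl(rep(3, 10)), 0)
  expect_equal(wl(c(0, 1, 0, 1)), 3)
  expect_equal(zc(c(1, -1, 1, -1)), 3)
  expect_equal(zc(c(2, 1, 3, 0.5)), 0)                     # strictly positive
  expect_equal(zc(c(0.001, -0.001)), 0)                    # below threshold
  expect_equal(ssc(c(1, 2, 3, 4, 5)), 0)                   # monotone
  expect_equal(ssc(c(0, 1, 0, 1, 0)), 3)
  expect_equal(sis(c(1, 2, 2)), 9)
  expect_equal(sis(rep(0, 4)), 0)
  expect_equal(norm_rsd(rep(2, 6), 1), 0)                  # constant window
  expect_equal(norm_rsd(c(0, 2, 0), 1), sqrt(8 / 3))
  expect_equal(norm_logdet(rep(1, 4)), 0.25)               # exp(0) / 4
  expect_equal(m_msr(c(4, 9, 16)), 3)
  expect_equal(m_msr(rep(0, 3)), 0)
  expect_equal(m_asm(rep(4, 4)), (3 * 2 + 4^0.75) / 4)
  expect_equal(m_asm(rep(0, 5)), 0)
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_equal(rms(rep(-2, 7)), 2)                         # |c| for constant
})

test_that("degenerate windows raise range errors", {
  expect_error(mav(numeric(0)), "empty")
  expect_error(wl(1), "2")
  expect_error(zc(1), "2")
  expect_error(ssc(c(1, 2)), "3")
  expect_error(norm_rsd(c(1, 2), 2), "short")
  expect_error(norm_rsd(1:5, 3), "order")
  expect_error(rms(numeric(0)), "empty")
})

test_that("composite vectors equal their components, in fixed order", {
  set.seed(1)
  for (i in 1:20) {
    x <- random_window(sample(10:200, 1))
    expect_equal(unname(td4_vector(x)), c(mav(x), wl(x), zc(x), ssc(x)))
    expect_equal(unname(ntdf_vector(x)),
                 c(sis(x), norm_rsd(x, 1), norm_rsd(x, 2), norm_logdet(x),
                   m_msr(x), m_asm(x)))
  }
  cst <- rep(2.5, 50)
  expect_equal(unname(td4_vector(cst)), c(2.5, 0, 0, 0))
  expect_equal(unname(ntdf_vector(cst))[2:3], c(0, 0))   # RSD1 = RSD2 = 0
})

test_that("all operators agree with explicit-loop oracles on random windows", {
  set.seed(7)
  for (i in 1:200) {
    x <- random_window(sample(5:300, 1)) * 10^sample(-3:3, 1)
    expect_equal(mav(x), oracle_mav(x), tolerance = 1e-9)
    expect_equal(wl(x), oracle_wl(x), tolerance = 1e-9)
    expect_equal(zc(x), oracle_zc(x))
    expect_equal(ssc(x), oracle_ssc(x))
    expect_equal(sis(x), oracle_sis(x), tolerance = 1e-9)
    expect_equal(norm_rsd(x, 1), oracle_norm_rsd(x, 1), tolerance = 1e-9)
    expect_equal(norm_rsd(x, 2), oracle_norm_rsd(x, 2), tolerance = 1e-9)
    expect_equal(norm_logdet(x), oracle_norm_logdet(x), tolerance = 1e-9)
    expect_equal(m_msr(x), oracle_m_msr(x), tolerance = 1e-9)
    expect_equal(m_asm(x), oracle_m_asm(x), tolerance = 1e-9)
    expect_equal(rms(x), oracle_rms(x), tolerance = 1e-9)
  }
})

test_that("amplitude scaling acts predictably on each feature", {
  set.seed(3)
  x <- random_window(120)
  cc <- 7.3
  expect_equal(mav(cc * x), cc * mav(x))
  expect_equal(wl(cc * x), cc * wl(x))
  expect_equal(rms(cc * x), cc * rms(x))
  expect_equal(sis(cc * x), cc^2 * sis(x))
  expect_equal(norm_logdet(cc * x), cc * norm_logdet(x), tolerance = 1e-6)
  p0 <- feature_params(0, 0)
  expect_equal(zc(cc * x, p0), zc(x, p0))   # threshold-free counts invariant
  expect_equal(ssc(cc * x, p0), ssc(x, p0))
})

test_that("feature matrices have the documented geometry and labels", {
  recs <- small_dataset()[1:3]              # one gesture, 3 trials
  fm <- build_feature_matrix(recs, srd_s = 1, feature_set = "TD4")
  expect_equal(dim(fm$values), c(3 * 9, 8 * 4))    # 9 windows x 32 columns
  expect_equal(colnames(fm$values)[1:5],
               c("ch1_MAV", "ch1_WL", "ch1_ZC", "ch1_SSC", "ch2_MAV"))
  expect_equal(ncol(build_feature_matrix(recs, 1, feature_set = "NTDF")$values),
               48)
  expect_equal(ncol(build_feature_matrix(recs, 1, feature_set = "RMS")$values),
               8)
  expect_true(all(fm$labels == recs[[1]]$class_code))
  expect_false(any(!is.finite(fm$values)))
})

test_that("disjoint recording sets concatenate to the union's matrix", {
  recs <- small_dataset()[1:6]
  fm_a <- build_feature_matrix(recs[1:3], 1, feature_set = "NTDF")
  fm_b <- build_feature_matrix(recs[4:6], 1, feature_set = "NTDF")
  fm_u <- build_feature_matrix(recs, 1, feature_set = "NTDF")
  expect_equal(unname(rbind(fm_a$values, fm_b$values)), unname(fm_u$values))
  expect_equal(c(fm_a$labels, fm_b$labels), fm_u$labels)
})

test_that("vectorized feature path equals per-window scalar operators", {
  rec <- small_dataset()[[10]]
  segs <- segment_windows(truncate_to_srd(rec, 1))
  wm <- segs[[3]]
  for (fset in names(feature_sets())) {
    block <- srdemg:::.feature_block(wm, fset)
    scalar_fn <- switch(fset, TD4 = td4_vector, NTDF = ntdf_vector,
                        RMS = function(x) c(RMS = rms(x)))
    ref <- do.call(rbind, lapply(seq_len(nrow(wm)),
                                 function(i) scalar_fn(wm[i, ])))
    expect_equal(unname(block), unname(ref), tolerance = 1e-12)
  }
})

test_that("mixed sampling rates are rejected", {
  r1 <- small_dataset()[[1]]
  r2 <- recording(r1$data, 2000, 1, "T", 1)
  expect_error(build_feature_matrix(list(r1, r2), 1), "sampling rate")
})

test_that("feature matrix round-trips losslessly through CSV + JSON", {
  fm <- build_feature_matrix(small_dataset()[1:4], 1, feature_set = "NTDF")
  stem <- file.path(withr::local_tempdir(), "fm")
  write_feature_matrix(fm, stem)
  back <- read_feature_matrix(stem)
  expect_equal(unname(back$values), unname(fm$values), tolerance = 1e-15)
  expect_equal(back$labels, fm$labels)
  expect_equal(back$meta$feature_set, fm$meta$feature_set)
  expect_equal(back$info$window_index, fm$info$window_index)
})
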
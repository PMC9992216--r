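test_that("classification accuracy matches hand counts and the loop oracle", {
  expect_equal(classification_accuracy(diag(5) * 7), 100)
  expect_equal(classification_accuracy(matrix(c(3, 1, 1, 3), 2)), 75)
  expect_error(classification_accuracy(matrix(0, 3, 3)), "empty")
  set.seed(2)
  for (i in 1:50) {
    cm <- random_confusion(sample(2:10, 1))
    expect_equal(classification_accuracy(cm), oracle_ca(cm))
  }
})

test_that("per-class MCC matches hand evaluation and conventions", {
  perfect <- diag(c(4, 6))
  expect_equal(mcc_per_class(perfect, 1), 1)
  inverted <- matrix(c(0, 4, 6, 0), 2)      # predictions fully swapped
  expect_equal(mcc_per_class(inverted, 1), -1)
  cm <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(mcc_per_class(cm, 1), 0.5)   # (9-1)/sqrt(4^4)
  expect_equal(mcc_per_class(cm, 2), 0.5)
  # zero denominator -> 0 by convention (no predictions for class 1)
  degenerate <- matrix(c(0, 0, 5, 5), 2)
  expect_equal(mcc_per_class(degenerate, 1), 0)
})

test_that("macro MCC averages classes, is bounded, and 1 iff diagonal", {
  expect_equal(mcc_macro(matrix(c(3, 1, 1, 3), 2)), 0.5)
  set.seed(4)
  for (i in 1:50) {
    cm <- random_confusion(sample(2:12, 1))
    m <- mcc_macro(cm)
    expect_equal(m, oracle_mcc_macro(cm), tolerance = 1e-12)
    expect_gte(m, -1); expect_lte(m, 1)
    diagonal <- all(cm[row(cm) != col(cm)] == 0) && all(diag(cm) > 0)
    expect_identical(m == 1, diagonal)
  }
  expect_equal(mcc_macro(diag(c(2, 3, 9))), 1)
})

test_that("per-gesture accuracy is the row-normalized diagonal", {
  expect_equal(unname(per_gesture_accuracy(diag(c(1, 5, 2)))), rep(100, 3))
  cm <- diag(c(5, 5, 5)); cm[2, ] <- c(5, 0, 0)   # class 2 never correct
  expect_equal(unname(per_gesture_accuracy(cm)), c(100, 0, 100))
  set.seed(5)
  for (i in 1:20) {
    cm <- random_confusion(5) + 1
    expect_equal(unname(per_gesture_accuracy(cm)), oracle_per_gesture(cm))
  }
})

test_that("Friedman test handles ties, forced orderings, and random tables", {
  tied <- matrix(5, nrow = 4, ncol = 3)
  ft <- friedman_test(tied)
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p_value, 1)
  # the same strict ordering in every block forces the rank sums
  forced <- rbind(c(10, 1, 5), c(9, 2, 6), c(8, 0, 4))
  expect_equal(friedman_test(forced)$statistic, 6)
  expect_error(friedman_test(matrix(1, 1, 3)), "blocks")
  set.seed(6)
  for (i in 1:30) {
    nb <- sample(2:8, 1); kt <- sample(2:6, 1)
    m <- matrix(stats::rnorm(nb * kt), nrow = nb)
    ref <- stats::friedman.test(m)
    got <- friedman_test(m)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-8)
    expect_equal(got$df, unname(ref$parameter))
  }
})

test_that("Within-SRD evaluation trains on trials 1+2 and tests trial 3", {
  recs <- easy_dataset()
  res <- within_srd_eval(recs, 2, "NTDF", classifier_spec("LDA"))
  expect_length(res, 1)
  r <- res[[1]]
  expect_equal(r$scenario, "within")
  expect_equal(r$srd_train, 2)
  # test set = trial 3 windows only: 15 gestures x 19 windows at 2 s
  expect_equal(r$n_test, 15 * n_windows(2000, 150, 100))
  expect_gt(r$ca, 90)            # separable settings decode accurately
  # determinism
  res2 <- within_srd_eval(recs, 2, "NTDF", classifier_spec("LDA"))
  expect_identical(results_table(res), results_table(res2))
  short <- recs[sapply(recs, function(x) x$trial_index < 3)]
  expect_error(within_srd_eval(short, 2), "3 trials")
})

test_that("Between-SRD prefix slicing equals truncate-then-extract", {
  recs <- small_dataset()[1:9]
  fm_full <- build_feature_matrix(recs, NULL, feature_set = "NTDF")
  for (srd in c(1, 2)) {
    nw <- n_windows(srd * 1000, 150, 100)
    sliced <- srdemg:::.fm_subset(fm_full, fm_full$info$window_index <= nw)
    direct <- build_feature_matrix(recs, srd, feature_set = "NTDF")
    expect_equal(unname(sliced$values), unname(direct$values),
                 tolerance = 1e-12)
    expect_equal(sliced$labels, direct$labels)
  }
})

test_that("faithful Between-SRD shares windows between train and test", {
  recs <- small_dataset()
  res <- between_srd_eval(recs, 5, "NTDF", classifier_spec("LDA"),
                          srd_test = c(1, 5))
  expect_length(res, 2)
  expect_equal(unname(sapply(res, function(r) r$srd_test)), c(1, 5))
  expect_equal(unique(sapply(res, function(r) r$scenario)), "between")
  # aggregate CA over test groups == window-count-weighted mean == pooled CA
  pooled <- classification_accuracy(pool_confusions(res))
  weighted <- sum(sapply(res, function(r) r$ca * r$n_test)) /
    sum(sapply(res, function(r) r$n_test))
  expect_equal(pooled, weighted, tolerance = 1e-10)
  # determinism
  res2 <- between_srd_eval(recs, 5, "NTDF", classifier_spec("LDA"),
                           srd_test = c(1, 5))
  expect_identical(results_table(res), results_table(res2))
})

test_that("strict Between-SRD holds out the last trial", {
  recs <- small_dataset()
  res <- between_srd_eval(recs, 2, "NTDF", classifier_spec("LDA"),
                          srd_test = 2, strict = TRUE)[[1]]
  expect_equal(res$scenario, "between_strict")
  # test set is trial 3 only
  expect_equal(res$n_test, 15 * n_windows(2000, 150, 100))
})

test_that("label permutation drops accuracy to 15-class chance", {
  recs <- small_dataset()
  fm_full <- build_feature_matrix(recs, 2, feature_set = "NTDF")
  tr <- fm_full$info$trial %in% c(1, 2)
  fm_train <- srdemg:::.fm_subset(fm_full, tr)
  fm_test <- srdemg:::.fm_subset(fm_full, !tr)
  set.seed(9)
  runs <- replicate(6, {
    fm_perm <- fm_train
    fm_perm$labels <- sample(fm_perm$labels)
    model <- train_model(fm_perm, classifier_spec("LDA"))
    cm <- confusion_matrix(fm_test$labels, predict_model(model, fm_test),
                           classes = sort(unique(fm_perm$labels)))
    c(classification_accuracy(cm), mcc_macro(cm))
  })
  ca_mean <- mean(runs[1, ]); ca_se <- sd(runs[1, ]) / sqrt(ncol(runs))
  mcc_mean <- mean(runs[2, ]); mcc_se <- sd(runs[2, ]) / sqrt(ncol(runs))
  expect_lt(abs(ca_mean - 100 / 15), 3 * ca_se + 1e-8)
  expect_lt(abs(mcc_mean), 3 * mcc_se + 1e-8)
})
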
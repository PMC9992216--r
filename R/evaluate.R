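#' Build a confusion matrix
#'
#' @param truth True class codes.
#' @param pred Predicted class codes.
#' @param classes Class order; default the sorted union of both.
#' @return Square integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, classes = sort(unique(c(truth, pred)))) {
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  t_ <- factor(truth, levels = classes)
  p_ <- factor(pred, levels = classes)
  m <- table(t_, p_)
  cm <- matrix(as.integer(m), nrow = length(classes),
               dimnames = list(true = classes, predicted = classes))
  cm
}

#' Classification accuracy from a confusion matrix
#'
#' @param cm Square count matrix (rows true, columns predicted).
#' @return Percent of correctly classified samples: `100 * trace / total`.
#' @export
classification_accuracy <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / total
}

#' One-vs-rest Matthews correlation coefficient for one class
#'
#' Binarizes class `j` against the rest and evaluates
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. If any factor of
#' the denominator is zero the coefficient is undefined and 0 is returned
#' (the standard convention).
#'
#' @param cm Square count matrix.
#' @param j Class index (1-based) or class name.
#' @return MCC in `[-1, 1]`.
#' @export
mcc_per_class <- function(cm, j) {
  if (is.character(j)) j <- match(j, rownames(cm))
  cm <- matrix(as.numeric(cm), nrow = nrow(cm))  # avoid integer overflow
  tp <- cm[j, j]
  fn <- sum(cm[j, ]) - tp
  fp <- sum(cm[, j]) - tp
  tn <- sum(cm) - tp - fn - fp
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  ((tp * tn) - (fp * fn)) / sqrt(den)
}

#' Macro-averaged Matthews correlation coefficient
#'
#' Mean of the one-vs-rest MCC over all classes of the confusion matrix.
#'
#' @param cm Square count matrix.
#' @return Macro MCC in `[-1, 1]`; 1 exactly when the matrix is diagonal with
#'   every class present.
#' @export
mcc_macro <- function(cm) {
  mean(vapply(seq_len(nrow(cm)), function(j) mcc_per_class(cm, j), numeric(1)))
}

#' Per-gesture recognition rate
#'
#' @param cm Square count matrix.
#' @return Named vector of per-class recall (row-normalized diagonal), in
#'   percent; `NaN` for classes absent from the test set.
#' @export
per_gesture_accuracy <- function(cm) {
  100 * diag(cm) / rowSums(cm)
}

#' Friedman rank test
#'
#' Nonparametric repeated-measures comparison of `k` treatments over `n`
#' blocks: within-block average ranks, chi-square statistic with the usual
#' tie correction, `k - 1` degrees of freedom. A table with complete ties in
#' every block returns statistic 0, p = 1.
#'
#' @param scores Numeric matrix, blocks in rows, treatments in columns.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
friedman_test <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2 || k < 2) stop("need >= 2 blocks and >= 2 treatments")
  if (any(!is.finite(scores))) stop("scores must be finite")
  r <- t(apply(scores, 1, rank))
  ties <- tapply(r, row(r), table)
  num <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) -
    sum(unlist(lapply(ties, function(u) u^3 - u))) / (k - 1)
  stat <- if (den <= 0) 0 else num / den
  list(statistic = stat, df = k - 1,
       p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

## ---- scenario evaluations ----

.result_row <- function(scenario, srd_train, srd_test, feature_set, spec,
                        subject, cm) {
  structure(
    list(scenario = scenario, srd_train = srd_train, srd_test = srd_test,
         feature_set = feature_set, classifier = spec$kind, subject = subject,
         ca = classification_accuracy(cm), mcc_macro = mcc_macro(cm),
         n_test = sum(cm), confusion = cm),
    class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<%s> subj=%s %s+%s train=%gs test=%gs  CA=%.2f%% MCC=%.3f (n=%d)\n",
              x$scenario, x$subject, x$feature_set, x$classifier,
              x$srd_train, x$srd_test, x$ca, x$mcc_macro, x$n_test))
  invisible(x)
}

.split_by_subject <- function(recordings) {
  split(recordings, vapply(recordings, function(r) as.character(r$subject_id),
                           character(1)))
}

# Window count of an SRD prefix for a sampling rate + segmentation.
.srd_nwin <- function(fs, srd_s, seg) {
  ws <- .win_samples(fs, seg)
  n_windows(round(fs * srd_s), ws$w, ws$s)
}

#' Precompute full-duration feature matrices per subject
#'
#' Because SRD groups are prefixes of the recording and windows never span
#' the truncation boundary, the windows of any SRD group are exactly the
#' leading windows of the full-duration segmentation. The scenario
#' evaluations therefore compute one feature matrix per subject at full
#' duration and slice SRD groups and trials out of it; this helper builds
#' that cache so it can be shared across classifiers and scenarios.
#'
#' @param recordings List of [recording()] objects.
#' @param feature_set `"NTDF"`, `"TD4"` or `"RMS"`.
#' @param seg A [segmentation_params()].
#' @param params A [feature_params()].
#' @return Named list (by subject) of full-duration `feature_matrix` objects.
#' @export
subject_feature_cache <- function(recordings, feature_set = "NTDF",
                                  seg = segmentation_params(),
                                  params = feature_params()) {
  lapply(.split_by_subject(recordings), build_feature_matrix,
         srd_s = NULL, seg = seg, feature_set = feature_set, params = params)
}

# Slice an SRD-group x trial-set subset out of a full-duration matrix.
.slice_srd <- function(fm, fs, srd_s, trials, seg) {
  keep <- fm$info$window_index <= .srd_nwin(fs, srd_s, seg) &
    fm$info$trial %in% trials
  .fm_subset(fm, keep, srd_s = srd_s)
}

#' Within-SRD evaluation
#'
#' For each subject: build feature vectors at the given SRD from trials 1 and
#' 2 (training set) and from trial 3 (test set), train the classifier, and
#' score the test predictions. Train and test come from the same SRD group.
#'
#' @param recordings List of [recording()] objects (>= 3 trials per subject
#'   per gesture).
#' @param srd_s SRD group length in seconds.
#' @param feature_set `"NTDF"`, `"TD4"` or `"RMS"`.
#' @param spec A [classifier_spec()].
#' @param seg A [segmentation_params()].
#' @param params A [feature_params()].
#' @param fm_cache Optional precomputed [subject_feature_cache()] for these
#'   recordings (skips feature extraction; `recordings` is then ignored).
#' @return List of `experiment_result`, one per subject.
#' @export
within_srd_eval <- function(recordings, srd_s, feature_set = "NTDF",
                            spec = classifier_spec(), seg = segmentation_params(),
                            params = feature_params(), fm_cache = NULL) {
  if (is.null(fm_cache))
    fm_cache <- subject_feature_cache(recordings, feature_set, seg, params)
  lapply(fm_cache, function(fm_full) {
    if (max(fm_full$info$trial) < 3)
      stop("Within-SRD evaluation needs >= 3 trials")
    fs <- fm_full$meta$fs
    fm_train <- .slice_srd(fm_full, fs, srd_s, c(1L, 2L), seg)
    fm_test <- .slice_srd(fm_full, fs, srd_s, 3L, seg)
    model <- train_model(fm_train, spec)
    pred <- predict_model(model, fm_test)
    cm <- confusion_matrix(fm_test$labels, pred,
                           classes = sort(unique(fm_train$labels)))
    .result_row("within", srd_s, srd_s, feature_set, spec,
                fm_full$info$subject[1], cm)
  })
}

#' Between-SRD evaluation
#'
#' For each subject: train at `srd_train` and score against every SRD group in
#' `srd_test`. In the faithful protocol both training and test feature
#' vectors are built from all trials, so training windows reappear in test
#' sets whose SRD overlaps the training prefix. The strict variant instead
#' trains on trials 1 and 2 and tests on trial 3 at every SRD.
#'
#' Because shorter SRDs are prefixes of longer ones, the full-duration
#' feature matrix is computed once per subject and SRD groups are taken as
#' window-index prefixes; this is exactly equivalent to truncating first and
#' windowing after.
#'
#' @inheritParams within_srd_eval
#' @param srd_train Training SRD group length, seconds.
#' @param srd_test SRD groups to test against (default all five).
#' @param strict Use the held-out-trial variant (default `FALSE`, the
#'   faithful protocol).
#' @return List of `experiment_result`, one per (subject, srd_test),
#'   subject-major.
#' @export
between_srd_eval <- function(recordings, srd_train, feature_set = "NTDF",
                             spec = classifier_spec(),
                             seg = segmentation_params(),
                             params = feature_params(),
                             srd_test = srd_groups(), strict = FALSE,
                             fm_cache = NULL) {
  if (is.null(fm_cache))
    fm_cache <- subject_feature_cache(recordings, feature_set, seg, params)
  out <- lapply(fm_cache, function(fm_full) {
    fs <- fm_full$meta$fs
    all_trials <- sort(unique(fm_full$info$trial))
    train_trials <- if (strict) setdiff(all_trials, max(all_trials)) else all_trials
    test_trials <- if (strict) max(all_trials) else all_trials
    model <- train_model(.slice_srd(fm_full, fs, srd_train, train_trials, seg),
                         spec)
    lapply(srd_test, function(srd_s) {
      fm_te <- .slice_srd(fm_full, fs, srd_s, test_trials, seg)
      pred <- predict_model(model, fm_te)
      cm <- confusion_matrix(fm_te$labels, pred, classes = model$classes)
      .result_row(if (strict) "between_strict" else "between",
                  srd_train, srd_s, feature_set, spec,
                  fm_full$info$subject[1], cm)
    })
  })
  unlist(out, recursive = FALSE)
}

#' Collect experiment results into a data frame
#'
#' @param results List of `experiment_result` objects.
#' @return Tidy data.frame, one row per result (confusion matrices dropped).
#' @export
results_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(scenario = r$scenario, srd_train = r$srd_train,
               srd_test = r$srd_test, feature_set = r$feature_set,
               classifier = r$classifier, subject = as.character(r$subject),
               ca = r$ca, mcc_macro = r$mcc_macro, n_test = r$n_test,
               stringsAsFactors = FALSE)))
}

#' Pool confusion matrices
#'
#' @param results List of `experiment_result` sharing a class set.
#' @return Elementwise sum of the confusion matrices.
#' @export
pool_confusions <- function(results) {
  Reduce(`+`, lapply(results, function(r) r$confusion))
}
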
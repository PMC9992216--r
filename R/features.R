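#' Feature extraction parameters
#'
#' @param zc_threshold Minimum amplitude swing for a zero crossing to count.
#' @param ssc_threshold Minimum slope product for a slope-sign change to count.
#' @return A `feature_params` object. Both thresholds default to 0.01.
#' @export
feature_params <- function(zc_threshold = 0.01, ssc_threshold = 0.01) {
  if (zc_threshold < 0 || ssc_threshold < 0) stop("thresholds must be >= 0")
  structure(list(zc_threshold = zc_threshold, ssc_threshold = ssc_threshold),
            class = "feature_params")
}

#' Feature set names and widths
#'
#' @return Named integer vector: features per channel for each supported set.
#' @export
feature_sets <- function() c(TD4 = 4L, NTDF = 6L, RMS = 1L)

## ---- scalar operators (one analysis window of one channel) ----

#' Mean absolute value of a window
#' @param x Numeric vector (window samples).
#' @return `(1/k) * sum(|x|)`.
#' @export
mav <- function(x) {
  if (length(x) < 1) stop("empty window")
  mean(abs(x))
}

#' Waveform length of a window
#' @param x Numeric vector.
#' @return Sum of absolute successive differences.
#' @export
wl <- function(x) {
  if (length(x) < 2) stop("window must have >= 2 samples")
  sum(abs(diff(x)))
}

#' Thresholded zero-crossing count
#'
#' Counts adjacent sample pairs whose signs differ and whose amplitude swing
#' is at least the threshold (Hudgins' definition).
#'
#' @param x Numeric vector.
#' @param params A [feature_params()].
#' @return Integer count.
#' @export
zc <- function(x, params = feature_params()) {
  if (length(x) < 2) stop("window must have >= 2 samples")
  a <- x[-length(x)]; b <- x[-1]
  sum(((a > 0 & b < 0) | (a < 0 & b > 0)) & abs(a - b) >= params$zc_threshold)
}

#' Thresholded slope-sign-change count
#'
#' Counts interior samples that are a local extremum with slope products on
#' both sides of at least the threshold (Hudgins' definition).
#'
#' @inheritParams zc
#' @return Integer count.
#' @export
ssc <- function(x, params = feature_params()) {
  k <- length(x)
  if (k < 3) stop("window must have >= 3 samples")
  mid <- x[2:(k - 1)]
  sum((mid - x[1:(k - 2)]) * (mid - x[3:k]) >= params$ssc_threshold)
}

#' Hudgins TD4 feature vector: (MAV, WL, ZC, SSC)
#' @inheritParams zc
#' @return Numeric vector of length 4 in fixed order.
#' @export
td4_vector <- function(x, params = feature_params()) {
  c(MAV = mav(x), WL = wl(x), ZC = zc(x, params), SSC = ssc(x, params))
}

#' Simple integral square (window energy)
#' @param x Numeric vector.
#' @return `sum(x^2)`.
#' @export
sis <- function(x) {
  if (length(x) < 1) stop("empty window")
  sum(x^2)
}

#' Normalized root squared descriptor of the first or second difference
#'
#' `sqrt((1/N) * sum(d^(order) x ^ 2))` with N the window length; captures
#' spectral information (difference operators weight high frequencies).
#'
#' @param x Numeric vector.
#' @param order 1 (first difference) or 2 (second difference).
#' @return Non-negative scalar.
#' @export
norm_rsd <- function(x, order = 1) {
  k <- length(x)
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  if (k < order + 1) stop("window too short for difference order")
  d <- diff(x, differences = order)
  sqrt(sum(d^2) / k)
}

#' Length-normalized log detector (geometric mean of |x|, divided by N)
#'
#' `exp(mean(log(|x| + eps))) / N`; for fixed window length this is a constant
#' monotone transform of the geometric mean, so the normalization choice is
#' classifier-irrelevant.
#'
#' @param x Numeric vector.
#' @param eps Guard added before the log (default 1e-12).
#' @return Non-negative scalar.
#' @export
norm_logdet <- function(x, eps = 1e-12) {
  k <- length(x)
  if (k < 1) stop("empty window")
  exp(mean(log(abs(x) + eps))) / k
}

#' Mean square-root amplitude
#'
#' `(1/k) * sum(|x|^(1/2))`; absolute value guards fractional powers of
#' negative samples.
#'
#' @param x Numeric vector.
#' @return Non-negative scalar.
#' @export
m_msr <- function(x) {
  if (length(x) < 1) stop("empty window")
  mean(sqrt(abs(x)))
}

#' Mean absolute-sample power-mean with position-dependent exponent
#'
#' `| sum(|x_n|^e(n)) | / k` where samples in the central half of the window
#' (0.25k <= n <= 0.75k, 1-based) take exponent 0.5 and the flanks 0.75.
#'
#' @param x Numeric vector.
#' @return Non-negative scalar.
#' @export
m_asm <- function(x) {
  k <- length(x)
  if (k < 1) stop("empty window")
  n <- seq_len(k)
  e <- ifelse(n >= 0.25 * k & n <= 0.75 * k, 0.5, 0.75)
  abs(sum(abs(x)^e)) / k
}

#' Six-descriptor NTDF feature vector
#'
#' (SIS, normRSD1, normRSD2, normLogDet, mMSR, mASM) in fixed order.
#'
#' @param x Numeric vector.
#' @return Numeric vector of length 6.
#' @export
ntdf_vector <- function(x) {
  c(SIS = sis(x), RSD1 = norm_rsd(x, 1), RSD2 = norm_rsd(x, 2),
    LOGDET = norm_logdet(x), MSR = m_msr(x), ASM = m_asm(x))
}

#' Root mean square of a window
#' @param x Numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  if (length(x) < 1) stop("empty window")
  sqrt(mean(x^2))
}

## ---- vectorized path over a window matrix (rows = windows) ----

# Computes the per-window feature block for one channel's window matrix.
# Must agree elementwise with the scalar operators above; a property test
# holds the two paths together.
.feature_block <- function(wm, feature_set, params = feature_params()) {
  k <- ncol(wm)
  aw <- abs(wm)
  d1 <- wm[, -1, drop = FALSE] - wm[, -k, drop = FALSE]
  switch(feature_set,
    TD4 = {
      a <- wm[, -k, drop = FALSE]; b <- wm[, -1, drop = FALSE]
      zc_n <- rowSums(((a > 0 & b < 0) | (a < 0 & b > 0)) &
                        abs(a - b) >= params$zc_threshold)
      mid <- wm[, 2:(k - 1), drop = FALSE]
      ssc_n <- rowSums((mid - wm[, 1:(k - 2), drop = FALSE]) *
                         (mid - wm[, 3:k, drop = FALSE]) >= params$ssc_threshold)
      cbind(MAV = rowMeans(aw), WL = rowSums(abs(d1)), ZC = zc_n, SSC = ssc_n)
    },
    NTDF = {
      d2 <- d1[, -1, drop = FALSE] - d1[, -(k - 1), drop = FALSE]
      n <- seq_len(k)
      e <- ifelse(n >= 0.25 * k & n <= 0.75 * k, 0.5, 0.75)
      cbind(SIS = rowSums(wm^2),
            RSD1 = sqrt(rowSums(d1^2) / k),
            RSD2 = sqrt(rowSums(d2^2) / k),
            LOGDET = exp(rowMeans(log(aw + 1e-12))) / k,
            MSR = rowMeans(sqrt(aw)),
            ASM = abs(rowSums(sweep(aw, 2, e, `^`))) / k)
    },
    RMS = cbind(RMS = sqrt(rowMeans(wm^2))),
    stop("unknown feature set: ", feature_set))
}

#' Build a feature matrix from recordings
#'
#' For each recording: truncate to the SRD, segment every channel into
#' overlapping windows, compute the chosen per-channel feature block, and
#' concatenate the 8 channel blocks channel-major (all of channel 1's
#' features, then channel 2's, ...). Rows are ordered by (recording,
#' window index) and labelled with the source recording's class code.
#'
#' @param recordings List of [recording()] objects sharing `fs`.
#' @param srd_s SRD truncation length in seconds, or `NULL` to use each
#'   recording in full.
#' @param seg A [segmentation_params()].
#' @param feature_set `"TD4"`, `"NTDF"` or `"RMS"`.
#' @param params A [feature_params()].
#' @return A `feature_matrix` object: list with `values` (n_windows x 8*d
#'   matrix, named columns `ch<i>_<feat>`), `labels` (class code per row), and
#'   `info` (data.frame: subject, class, trial, window_index per row), plus
#'   `meta` (feature set, srd, segmentation).
#' @export
build_feature_matrix <- function(recordings, srd_s = NULL,
                                 seg = segmentation_params(),
                                 feature_set = c("NTDF", "TD4", "RMS"),
                                 params = feature_params()) {
  feature_set <- match.arg(feature_set)
  if (length(recordings) == 0) stop("no recordings supplied")
  fs <- unique(vapply(recordings, function(r) r$fs, numeric(1)))
  if (length(fs) != 1) stop("recordings must share a sampling rate")
  blocks <- vector("list", length(recordings))
  infos <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    if (!is.null(srd_s)) rec <- truncate_to_srd(rec, srd_s)
    segs <- segment_windows(rec, seg)
    chan <- lapply(segs, .feature_block, feature_set = feature_set, params = params)
    vals <- do.call(cbind, chan)
    colnames(vals) <- as.vector(t(outer(seq_len(8),
                                        colnames(chan[[1]]),
                                        function(i, f) paste0("ch", i, "_", f))))
    blocks[[i]] <- vals
    infos[[i]] <- data.frame(subject = rec$subject_id, class = rec$class_code,
                             trial = rec$trial_index,
                             window_index = seq_len(nrow(vals)),
                             stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, blocks)
  info <- do.call(rbind, infos)
  if (any(!is.finite(values))) stop("feature matrix contains non-finite values")
  structure(
    list(values = values, labels = info$class, info = info,
         meta = list(feature_set = feature_set, srd_s = srd_s, fs = fs,
                     seg = seg)),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d windows x %d features, %d classes (srd=%s)\n",
              x$meta$feature_set, nrow(x$values), ncol(x$values),
              length(unique(x$labels)),
              if (is.null(x$meta$srd_s)) "full" else paste0(x$meta$srd_s, "s")))
  invisible(x)
}

# Row-subset a feature matrix (used for SRD prefix slicing and trial splits).
.fm_subset <- function(fm, rows, srd_s = fm$meta$srd_s) {
  structure(
    list(values = fm$values[rows, , drop = FALSE],
         labels = fm$labels[rows],
         info = fm$info[rows, , drop = FALSE],
         meta = utils::modifyList(fm$meta, list(srd_s = srd_s))),
    class = "feature_matrix")
}
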
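#' Segmentation parameters
#'
#' Overlapping analysis windows: 150 ms length stepped by 100 ms by default,
#' the common choice for pattern-recognition myocontrol.
#'
#' @param window_ms Window length in milliseconds.
#' @param increment_ms Step between consecutive window starts, milliseconds.
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(window_ms = 150, increment_ms = 100) {
  if (increment_ms <= 0 || increment_ms > window_ms)
    stop("need 0 < increment_ms <= window_ms")
  structure(list(window_ms = window_ms, increment_ms = increment_ms),
            class = "segmentation_params")
}

#' Standard SRD groups
#'
#' Signal recording duration groups, in seconds, compared by the experiment
#' grid.
#' @return Numeric vector `c(1, 5, 10, 15, 20)`.
#' @export
srd_groups <- function() c(1, 5, 10, 15, 20)

# Forward-backward filtering with reflection padding: mirrored extensions at
# both ends absorb the filter's startup transients (the notch at Q = 30 rings
# for ~200 samples), then the pad is trimmed off.
.zero_phase <- function(filt, x, pad = min(length(x) - 1, 1000)) {
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[length(x)] -
            x[(length(x) - 1):(length(x) - pad)])
  y <- signal::filtfilt(filt, xp)
  y[(pad + 1):(pad + length(x))]
}

# Zero-phase acquisition band-pass, shared by the generator and the
# preprocessing filter: 4th-order Butterworth high-pass at the low edge
# cascaded with an 8th-order Butterworth low-pass at the high edge. The
# cascade is better conditioned than a single narrow band-pass when the low
# edge sits far below Nyquist, and its low-pass skirt is steep enough that a
# 500 Hz tone at 4 kHz sampling keeps < 5% of its power.
.acq_bandpass <- function(x, fs, low_hz, high_hz) {
  hp <- signal::butter(4, low_hz / (fs / 2), type = "high")
  lp <- signal::butter(8, high_hz / (fs / 2), type = "low")
  .zero_phase(lp, .zero_phase(hp, x))
}

# RBJ biquad notch (b, a) at f0 Hz with quality factor Q.
.notch_coef <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Band-pass and notch filter a recording
#'
#' Butterworth band-pass (4th-order high-pass, 8th-order low-pass cascade)
#' plus a 2nd-order IIR notch (Q = 30) for power-line interference, all
#' applied forward-backward (zero phase) so window boundaries are not phase
#' shifted.
#'
#' @param rec A [recording()].
#' @param low_hz,high_hz Pass-band edges in Hz.
#' @param notch_hz Power-line frequency to reject (50 by default; set 60 for
#'   60 Hz mains). `NULL` disables the notch.
#' @return A filtered [recording()] of identical shape.
#' @export
bandpass_notch <- function(rec, low_hz = 20, high_hz = 450, notch_hz = 50) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("invalid band: need 0 < low < high < fs/2")
  if (!is.null(notch_hz) && !(notch_hz > 0 && notch_hz < nyq))
    stop("notch frequency must lie in (0, fs/2)")
  nc <- if (is.null(notch_hz)) NULL else .notch_coef(notch_hz, rec$fs)
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    y <- .acq_bandpass(out[ch, ], rec$fs, low_hz, high_hz)
    if (!is.null(nc)) y <- .zero_phase(signal::Arma(b = nc$b, a = nc$a), y)
    out[ch, ] <- y
  }
  recording(out, rec$fs, rec$subject_id, rec$class_code, rec$trial_index)
}

#' Truncate a recording to an SRD group
#'
#' Keeps the first `length_s` seconds (prefix truncation, matching the nested
#' depiction of shorter recording durations inside longer ones). Set
#' `offset_s` for a random/fixed-offset crop instead.
#'
#' @param rec A [recording()].
#' @param length_s Target duration in seconds.
#' @param offset_s Start offset in seconds (default 0 = prefix).
#' @return The truncated [recording()].
#' @export
truncate_to_srd <- function(rec, length_s, offset_s = 0) {
  stopifnot(inherits(rec, "recording"))
  n <- round(rec$fs * length_s)
  i0 <- round(rec$fs * offset_s)
  if (i0 + n > ncol(rec$data))
    stop("requested SRD exceeds recording duration")
  if (n < 1) stop("length_s too short for this sampling rate")
  recording(rec$data[, (i0 + 1):(i0 + n), drop = FALSE], rec$fs,
            rec$subject_id, rec$class_code, rec$trial_index)
}

#' Number of analysis windows in a signal
#'
#' @param n_samples Signal length in samples.
#' @param w Window length in samples.
#' @param s Step in samples.
#' @return `floor((n_samples - w) / s) + 1`; 0 if the signal is shorter than
#'   one window.
#' @export
n_windows <- function(n_samples, w, s) {
  if (n_samples < w) return(0L)
  as.integer((n_samples - w) %/% s + 1L)
}

# Window length / step in samples for a recording + params.
.win_samples <- function(fs, params) {
  list(w = round(fs * params$window_ms / 1000),
       s = round(fs * params$increment_ms / 1000))
}

#' Segment one channel into an overlapping-window matrix
#'
#' @param x Numeric vector (one channel).
#' @param w Window length in samples.
#' @param s Step in samples.
#' @return `n_win x w` matrix; row i holds samples
#'   `(i-1)*s + 1 ... (i-1)*s + w`. Trailing samples that cannot fill a
#'   window are dropped.
#' @export
window_matrix <- function(x, w, s) {
  nw <- n_windows(length(x), w, s)
  if (nw == 0) stop("signal shorter than one analysis window")
  idx <- outer((seq_len(nw) - 1L) * s, seq_len(w), `+`)
  matrix(x[idx], nrow = nw)
}

#' Segment a recording into labelled windows
#'
#' Splits every channel of `rec` into overlapping analysis windows. Windows
#' are built after any SRD truncation, so no window spans a truncation
#' boundary.
#'
#' @param rec A [recording()].
#' @param params A [segmentation_params()].
#' @return List with one element per channel; each element is the `n_win x w`
#'   window matrix of [window_matrix()]. Attributes `class_code`, `w`, `s`
#'   carry the label and geometry.
#' @export
segment_windows <- function(rec, params = segmentation_params()) {
  stopifnot(inherits(rec, "recording"), inherits(params, "segmentation_params"))
  ws <- .win_samples(rec$fs, params)
  if (ncol(rec$data) < ws$w) stop("recording shorter than one analysis window")
  out <- lapply(seq_len(nrow(rec$data)),
                function(ch) window_matrix(rec$data[ch, ], ws$w, ws$s))
  attr(out, "class_code") <- rec$class_code
  attr(out, "w") <- ws$w
  attr(out, "s") <- ws$s
  out
}
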
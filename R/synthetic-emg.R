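#' Simulation configuration
#'
#' Bundles the acquisition-protocol parameters the generator emulates: an
#' 8-channel forearm montage sampled at `fs` Hz, `duration_s` seconds of
#' active contraction per gesture per trial, band-limited 20--450 Hz content,
#' plus the knobs that control how hard the decoding problem is.
#'
#' @param n_subjects Number of simulated subjects.
#' @param n_trials Trials per subject per gesture (default 3).
#' @param fs Sampling rate in Hz (default 4000).
#' @param duration_s Active recording length per gesture per trial, seconds
#'   (default 20).
#' @param band Pass band `c(low, high)` in Hz of the carrier (default 20--450).
#' @param snr_db Signal-to-noise ratio, in dB, of the class-modulated carrier
#'   relative to the additive broadband noise. Default 5 dB, a moderate
#'   surface-EMG quality that keeps the 15-gesture problem challenging.
#' @param drift_strength Non-negative scalar controlling fatigue-like drift:
#'   a monotone amplitude gain plus a progressive shift of spectral weight
#'   toward low frequencies over the recording. 0 disables drift. Default 1.
#' @param subject_variability Relative sd of the per-subject multiplicative
#'   perturbation of channel gains (default 0.15).
#' @param trial_variability Relative sd of the per-trial gain perturbation
#'   (default 0.2; electrode seating and posture change a little between
#'   trials).
#' @param seed Master integer seed; all per-recording substreams derive from it.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_subjects = 1L, n_trials = 3L, fs = 4000,
                       duration_s = 20, band = c(20, 450), snr_db = 5,
                       drift_strength = 1, subject_variability = 0.15,
                       trial_variability = 0.2, seed = 1L) {
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
         fs = fs, duration_s = duration_s, band = as.numeric(band),
         snr_db = snr_db, drift_strength = drift_strength,
         subject_variability = subject_variability,
         trial_variability = trial_variability, seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$band) != 2 || cfg$band[1] <= 0 || cfg$band[1] >= cfg$band[2])
    stop("invalid band: need 0 < low < high")
  if (cfg$fs <= 2 * cfg$band[2])
    stop("fs must exceed twice the band upper edge (fs > 2*high)")
  if (cfg$duration_s <= 0) stop("duration_s must be positive")
  if (cfg$n_trials < 1) stop("n_trials must be >= 1")
  if (cfg$n_subjects < 1) stop("n_subjects must be >= 1")
  if (cfg$drift_strength < 0) stop("drift_strength must be >= 0")
  if (cfg$subject_variability < 0 || cfg$trial_variability < 0)
    stop("variability parameters must be >= 0")
  invisible(cfg)
}

#' Construct a recording object
#'
#' @param data 8 x N numeric matrix, channels in rows.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param class_code Gesture class code.
#' @param trial_index Trial number (1-based).
#' @return A `recording` object.
#' @export
recording <- function(data, fs, subject_id, class_code, trial_index) {
  data <- as.matrix(data)
  if (nrow(data) != 8) stop("recordings carry exactly 8 channels (rows)")
  if (any(!is.finite(data))) stop("recording data must be finite")
  structure(
    list(data = data, fs = fs, subject_id = subject_id,
         class_code = class_code, trial_index = as.integer(trial_index)),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject=%s class=%s trial=%d  8 x %d @ %g Hz (%.3g s)\n",
              x$subject_id, x$class_code, x$trial_index, ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

# Per-subject multiplicative gain perturbation, stable across all of that
# subject's recordings under a given master seed.
.subject_gain_perturbation <- function(cfg, subject_id) {
  .with_seed(.substream_seed(cfg$seed, "subject", subject_id),
             function() exp(stats::rnorm(8, 0, cfg$subject_variability)))
}

# Fatigue target pattern: the class pattern blended toward a uniform
# distribution of the same total power, emulating synergist co-recruitment
# and load redistribution during sustained contraction. Classes converge
# toward one another as fatigue progresses.
.fatigue_pattern <- function(gains) {
  rep(sqrt(sum(gains^2) / length(gains)), length(gains))
}

# Band-limited unit-RMS Gaussian carrier: white noise through the same
# zero-phase Butterworth cascade the preprocessing filter uses, so generated
# content sits cleanly inside the acquisition band.
.bandlimited_carrier <- function(n, fs, band) {
  x <- .acq_bandpass(stats::rnorm(n), fs, band[1], band[2])
  x / stats::sd(x)
}

#' Generate one synthetic EMG recording
#'
#' Each channel is a band-limited Gaussian carrier amplitude-modulated by the
#' profile's channel gain, the activation envelope, and per-subject / per-trial
#' multiplicative perturbations; broadband Gaussian noise is added at
#' `snr_db`. With `drift_strength > 0` the recording additionally drifts to
#' emulate fatigue during a sustained contraction: amplitude grows linearly
#' with time, spectral weight shifts toward low frequencies (a time-varying
#' blend with a variance-matched 80 Hz low-pass copy of the carrier), and the
#' spatial activation pattern progressively flattens toward a common
#' equal-power distribution across channels, so gesture patterns become less
#' distinct late in the recording.
#'
#' Deterministic given `(cfg$seed, subject_id, class_code, trial_index)`.
#'
#' @param profile A [gesture_profile()].
#' @param cfg A [sim_config()].
#' @param subject_id Subject identifier.
#' @param trial_index Trial number.
#' @return A [recording()].
#' @export
generate_recording <- function(profile, cfg, subject_id = 1L, trial_index = 1L) {
  validate_sim_config(cfg)
  if (!inherits(profile, "gesture_profile")) stop("profile must be a gesture_profile")
  n <- round(cfg$fs * cfg$duration_s)
  subj_gain <- .subject_gain_perturbation(cfg, subject_id)
  rs <- .substream_seed(cfg$seed, "rec", subject_id, profile$class_code, trial_index)
  .with_seed(rs, function() {
    trial_gain <- exp(stats::rnorm(8, 0, cfg$trial_variability))
    tt <- seq_len(n) / n                     # normalized time in (0, 1]
    env <- .envelope(profile$envelope_shape, tt)
    sig <- matrix(0, nrow = 8, ncol = n)
    drift_on <- cfg$drift_strength > 0
    lp <- if (drift_on) signal::butter(2, 80 / (cfg$fs / 2), type = "low")
    # Drift progress u ramps over the first half of the recording at
    # drift_strength = 1 and saturates; spectral blend follows u, spatial
    # pattern flattening accelerates late (u^2) as fatigue compounds, and
    # amplitude grows linearly over the whole recording.
    u <- if (drift_on) pmin(1, 2 * cfg$drift_strength * tt) else 0
    q <- 0.8 * u^2
    fat <- .fatigue_pattern(profile$channel_gains)
    for (ch in 1:8) {
      x <- .bandlimited_carrier(n, cfg$fs, cfg$band)
      gain_t <- profile$channel_gains[ch]
      if (drift_on) {
        xl <- .zero_phase(lp, x)
        xl <- xl / stats::sd(xl)             # variance-matched low-pass copy
        m <- 0.7 * u
        x <- (1 - m) * x + m * xl
        x <- x * (1 + 0.7 * cfg$drift_strength * tt)
        gain_t <- (1 - q) * gain_t + q * fat[ch]   # spatial pattern flattening
      }
      sig[ch, ] <- gain_t * subj_gain[ch] * trial_gain[ch] * env * x
    }
    # Additive noise shares the acquisition band: the emulated recording
    # chain band-passes everything before storage, so stored noise is
    # broadband within 20-450 Hz, not white to Nyquist.
    p_sig <- mean(apply(sig, 1, stats::var))
    noise_sd <- sqrt(p_sig / 10^(cfg$snr_db / 10))
    for (ch in 1:8)
      sig[ch, ] <- sig[ch, ] + noise_sd * .bandlimited_carrier(n, cfg$fs, cfg$band)
    recording(sig, cfg$fs, subject_id, profile$class_code, trial_index)
  })
}

#' Generate the full factorial synthetic dataset
#'
#' Produces `n_subjects x 15 gestures x n_trials` recordings. Each recording
#' is drawn from its own seeded substream, so any element of the returned list
#' can be regenerated in isolation with [generate_recording()].
#'
#' @param cfg A [sim_config()].
#' @param profiles Profile set, default [default_profiles()] seeded from
#'   `cfg$seed`.
#' @return List of [recording()] objects, ordered subject-major, then gesture
#'   (canonical code order), then trial.
#' @export
generate_dataset <- function(cfg, profiles = default_profiles(cfg$seed)) {
  validate_sim_config(cfg)
  out <- vector("list", cfg$n_subjects * length(profiles) * cfg$n_trials)
  i <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    for (code in names(profiles)) {
      for (tr in seq_len(cfg$n_trials)) {
        i <- i + 1L
        out[[i]] <- generate_recording(profiles[[code]], cfg,
                                       subject_id = s, trial_index = tr)
      }
    }
  }
  out
}
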
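#' Gesture class codes
#'
#' The fifteen finger-motion classes handled by the pipeline: flexion of the
#' five individual fingers (T, I, M, R, L), nine two/three-finger combinations,
#' and hand close (HC).
#'
#' @return Character vector of the 15 class codes, in canonical order.
#' @export
gesture_codes <- function() {
  c("T", "I", "M", "R", "L",
    "TI", "TM", "TR", "TL", "HC",
    "IM", "MR", "RL", "IMR", "MRL")
}

# Per-finger base activation over the 8 forearm channels. Each single finger
# loads a contiguous group of electrodes with Gaussian falloff; combined
# gestures superpose the constituent fingers. HC loads everything.
.finger_channel_centers <- c(T = 1.5, I = 3.0, M = 4.5, R = 6.0, L = 7.5)

.finger_gain <- function(finger, width = 2.0) {
  ch <- seq_len(8)
  g <- exp(-((ch - .finger_channel_centers[[finger]])^2) / (2 * width^2))
  g / sqrt(sum(g^2))
}

.code_fingers <- function(code) {
  if (code == "HC") return(c("T", "I", "M", "R", "L"))
  strsplit(code, "")[[1]]
}

#' Construct the default gesture profile set
#'
#' Builds one profile per gesture code. Each profile carries eight non-negative
#' channel gains: single-finger classes load a contiguous electrode group,
#' multi-finger classes superpose their constituent fingers, and a small
#' seeded multiplicative jitter keeps all 15 gain vectors pairwise distinct
#' while remaining deterministic for a given seed.
#'
#' @param seed Integer seed controlling the jitter.
#' @param jitter_sd Relative standard deviation of the per-channel jitter.
#' @param envelope Activation envelope shape, `"constant"` or `"trapezoid"`.
#' @return Named list of `gesture_profile` objects, one per code.
#' @export
default_profiles <- function(seed = 0L, jitter_sd = 0.05, envelope = "constant") {
  codes <- gesture_codes()
  profiles <- vector("list", length(codes))
  names(profiles) <- codes
  for (i in seq_along(codes)) {
    code <- codes[i]
    fingers <- .code_fingers(code)
    g <- rowSums(vapply(fingers, .finger_gain, numeric(8)))
    g <- g / sqrt(sum(g^2))
    rs <- .substream_seed(seed, "profile", code)
    jitter <- .with_seed(rs, function() exp(stats::rnorm(8, 0, jitter_sd)))
    g <- g * jitter
    profiles[[i]] <- gesture_profile(code, g, envelope)
  }
  profiles
}

#' Create a gesture profile
#'
#' @param class_code One of [gesture_codes()].
#' @param channel_gains Eight non-negative amplitude multipliers.
#' @param envelope_shape `"constant"` or `"trapezoid"`.
#' @return A `gesture_profile` object.
#' @export
gesture_profile <- function(class_code, channel_gains,
                            envelope_shape = c("constant", "trapezoid")) {
  envelope_shape <- match.arg(envelope_shape)
  if (!is.character(class_code) || length(class_code) != 1)
    stop("class_code must be a single string")
  if (length(channel_gains) != 8)
    stop("channel_gains must have exactly 8 elements")
  if (any(channel_gains < 0) || !all(is.finite(channel_gains)))
    stop("channel_gains must be finite and non-negative")
  if (all(channel_gains == 0))
    stop("at least one channel gain must be positive")
  structure(
    list(class_code = class_code,
         channel_gains = as.numeric(channel_gains),
         envelope_shape = envelope_shape),
    class = "gesture_profile")
}

# Evaluate the activation envelope at normalized times t in [0, 1].
.envelope <- function(shape, t) {
  switch(shape,
    constant = rep(1, length(t)),
    trapezoid = pmin(1, pmin(t, 1 - t) / 0.1),
    stop("unknown envelope shape: ", shape))
}
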
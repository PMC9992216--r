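# Independent explicit-loop oracles for every feature operator. These stay
# deliberately naive (index loops, no vectorization) so they share nothing
# with the implementation they check.

oracle_mav <- function(x) {
  s <- 0
  for (n in seq_along(x)) s <- s + abs(x[n])
  s / length(x)
}

oracle_wl <- function(x) {
  s <- 0
  for (n in 1:(length(x) - 1)) s <- s + abs(x[n + 1] - x[n])
  s
}

oracle_zc <- function(x, thr = 0.01) {
  cnt <- 0
  for (n in 1:(length(x) - 1)) {
    opposite <- (x[n] > 0 && x[n + 1] < 0) || (x[n] < 0 && x[n + 1] > 0)
    if (opposite && abs(x[n] - x[n + 1]) >= thr) cnt <- cnt + 1
  }
  cnt
}

oracle_ssc <- function(x, thr = 0.01) {
  cnt <- 0
  for (n in 2:(length(x) - 1)) {
    if ((x[n] - x[n - 1]) * (x[n] - x[n + 1]) >= thr) cnt <- cnt + 1
  }
  cnt
}

oracle_sis <- function(x) {
  s <- 0
  for (n in seq_along(x)) s <- s + x[n]^2
  s
}

oracle_norm_rsd <- function(x, order) {
  d <- x
  for (i in seq_len(order)) {
    dn <- numeric(length(d) - 1)
    for (n in 1:(length(d) - 1)) dn[n] <- d[n + 1] - d[n]
    d <- dn
  }
  s <- 0
  for (n in seq_along(d)) s <- s + d[n]^2
  sqrt(s / length(x))
}

oracle_norm_logdet <- function(x, eps = 1e-12) {
  s <- 0
  for (n in seq_along(x)) s <- s + log(abs(x[n]) + eps)
  exp(s / length(x)) / length(x)
}

oracle_m_msr <- function(x) {
  s <- 0
  for (n in seq_along(x)) s <- s + abs(x[n])^0.5
  s / length(x)
}

oracle_m_asm <- function(x) {
  k <- length(x)
  s <- 0
  for (n in 1:k) {
    e <- if (n >= 0.25 * k && n <= 0.75 * k) 0.5 else 0.75
    s <- s + abs(x[n])^e
  }
  abs(s) / k
}

oracle_rms <- function(x) {
  s <- 0
  for (n in seq_along(x)) s <- s + x[n]^2
  sqrt(s / length(x))
}

# Brute-force sliding window counter: slides a start index and counts
# placements that fit entirely inside the signal.
oracle_window_count <- function(n_samples, w, s) {
  cnt <- 0
  start <- 1
  while (start + w - 1 <= n_samples) {
    cnt <- cnt + 1
    start <- start + s
  }
  cnt
}

oracle_ca <- function(cm) {
  correct <- 0
  for (i in seq_len(nrow(cm))) correct <- correct + cm[i, i]
  100 * correct / sum(cm)
}

oracle_mcc_macro <- function(cm) {
  k <- nrow(cm)
  total <- 0
  for (j in 1:k) {
    tp <- as.numeric(cm[j, j])
    fn <- sum(cm[j, ]) - tp
    fp <- sum(cm[, j]) - tp
    tn <- sum(cm) - tp - fn - fp
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    total <- total + if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  }
  total / k
}

oracle_per_gesture <- function(cm) {
  out <- numeric(nrow(cm))
  for (i in seq_len(nrow(cm))) out[i] <- 100 * cm[i, i] / sum(cm[i, ])
  out
}
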
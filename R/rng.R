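# Deterministic substream seeding.
#
# Every stochastic object (a recording, a subject's gain perturbation, a
# profile's jitter) draws from its own substream whose seed is a stable hash
# of the master seed and the object's identity. Any single recording is then
# reproducible in isolation, without replaying the whole dataset.

# Polynomial string hash folded into [0, 2^31 - 2]; stable across platforms
# because it only uses integer character codes and double arithmetic below 2^53.
.substream_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, character(1))),
               collapse = "\r")
  h <- 0
  m <- 2147483647  # 2^31 - 1, prime
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Run fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
.with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
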
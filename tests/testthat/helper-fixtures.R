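# Shared synthetic fixtures, built lazily and cached for the whole run.
# Sizes are desk scale: 1000 Hz sampling keeps the 150/100 ms window geometry
# (same window counts as 4000 Hz) at a quarter of the samples.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 15 gestures x 3 trials, 1 subject, 5 s, default difficulty.
small_dataset <- function() {
  fixture("small_dataset", function() {
    generate_dataset(sim_config(n_subjects = 1, fs = 1000, duration_s = 5,
                                seed = 11))
  })
}

# As above, easy mode: high SNR, no drift, quiet trials. Separable.
easy_dataset <- function() {
  fixture("easy_dataset", function() {
    generate_dataset(sim_config(n_subjects = 1, fs = 1000, duration_s = 5,
                                snr_db = 25, drift_strength = 0,
                                trial_variability = 0.05, seed = 3))
  })
}

# Small labelled feature matrix for classifier tests.
small_fm <- function(feature_set = "NTDF") {
  fixture(paste0("small_fm_", feature_set), function() {
    build_feature_matrix(small_dataset(), srd_s = 2,
                         feature_set = feature_set)
  })
}

random_window <- function(k = 150) stats::rnorm(k)

# Two well-separated Gaussian point clouds as a feature_matrix.
cloud_fm <- function(n = 30, p = 4, gap = 10, seed = 1, labels = c("A", "B")) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n * p), n),
             matrix(stats::rnorm(n * p, mean = gap), n))
  colnames(x) <- paste0("f", 1:p)
  structure(list(values = x, labels = rep(labels, each = n),
                 info = data.frame(subject = 1, class = rep(labels, each = n),
                                   trial = 1, window_index = seq_len(2 * n)),
                 meta = list(feature_set = "TD4", srd_s = NULL, fs = 1000,
                             seg = segmentation_params())),
            class = "feature_matrix")
}

random_confusion <- function(k = 6, lambda = 8) {
  matrix(stats::rpois(k * k, lambda), k,
         dimnames = list(true = letters[1:k], predicted = letters[1:k]))
}
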
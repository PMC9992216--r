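#!/usr/bin/env Rscript
# Step 1: simulate the study's recording protocol at desk scale and write the
# dataset to disk (one CSV + JSON sidecar per recording, plus a manifest).
#
# Conditions: 15 finger gestures x 3 trials x 20 s active contraction per
# recording, 8 channels, fatigue drift on, moderate SNR. Desk scale means
# 1000 Hz sampling (the 150/100 ms window geometry is preserved) and 2
# subjects; pass --paper-scale for 8 subjects at 4000 Hz.

library(srdemg)

args <- commandArgs(trailingOnly = TRUE)
paper_scale <- "--paper-scale" %in% args

cfg <- if (paper_scale) {
  sim_config(n_subjects = 8, fs = 4000, seed = 1)
} else {
  sim_config(n_subjects = 2, fs = 1000, seed = 1)
}

message(sprintf("simulating %d subjects x 15 gestures x %d trials at %g Hz ...",
                cfg$n_subjects, cfg$n_trials, cfg$fs))
recs <- generate_dataset(cfg)
manifest <- write_dataset(recs, "scratch/dataset")
message(sprintf("wrote %d recordings; manifest: %s", length(recs), manifest))
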
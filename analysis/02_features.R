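#!/usr/bin/env Rscript
# Step 2: band-pass + notch filter the simulated dataset and extract the
# three feature sets (NTDF, TD4, RMS) over 150/100 ms overlapping windows at
# full recording duration. Feature matrices are written per subject and
# feature set; SRD groups are window-index prefixes of these, so every later
# step slices rather than recomputing.

library(srdemg)

recs <- read_dataset("scratch/dataset/manifest.json")
message(sprintf("loaded %d recordings", length(recs)))
recs <- lapply(recs, bandpass_notch)

for (fset in names(feature_sets())) {
  cache <- subject_feature_cache(recs, fset)
  for (subj in names(cache)) {
    stem <- file.path("scratch/features", sprintf("%s_subject%s", fset, subj))
    write_feature_matrix(cache[[subj]], stem)
    message(sprintf("%s subject %s: %d windows x %d features -> %s.csv",
                    fset, subj, nrow(cache[[subj]]$values),
                    ncol(cache[[subj]]$values), stem))
  }
}
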
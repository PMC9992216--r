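#!/usr/bin/env Rscript
# Step 3: the Within-SRD scenario — train on trials 1+2, test on trial 3,
# with train and test drawn from the same recording-duration group. This is
# the conventional protocol in myocontrol studies; it measures how well a
# duration characterizes gestures when conditions match.

library(srdemg)

recs <- lapply(read_dataset("scratch/dataset/manifest.json"), bandpass_notch)

rows <- list()
for (fset in c("NTDF", "TD4", "RMS")) {
  cache <- subject_feature_cache(recs, fset)
  for (clf in list(classifier_spec("LDA"), classifier_spec("KNN"),
                   classifier_spec("RF", n_trees = 50))) {
    for (srd in srd_groups()) {
      res <- within_srd_eval(recs, srd, fset, clf, fm_cache = cache)
      rows[[length(rows) + 1]] <- results_table(res)
    }
  }
}
results <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(results, "results/within_srd.csv", row.names = FALSE, quote = FALSE)

agg <- aggregate(ca ~ srd_train + feature_set + classifier, results, mean)
message("Within-SRD mean CA (%) by duration:")
print(reshape(agg, direction = "wide", idvar = c("feature_set", "classifier"),
              timevar = "srd_train"), row.names = FALSE)
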
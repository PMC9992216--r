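#!/usr/bin/env Rscript
# Step 4: the Between-SRD scenario — train at one duration group (all
# trials), test against every duration group. This is the study's proxy for
# practical deployment: the duration used for calibration rarely matches
# what the prosthesis sees later. The headline question is which training
# duration generalizes best.

library(srdemg)

recs <- lapply(read_dataset("scratch/dataset/manifest.json"), bandpass_notch)

rows <- list()
for (fset in c("NTDF", "TD4", "RMS")) {
  cache <- subject_feature_cache(recs, fset)
  for (clf in list(classifier_spec("LDA"), classifier_spec("KNN"),
                   classifier_spec("RF", n_trees = 50))) {
    for (srd in srd_groups()) {
      res <- between_srd_eval(recs, srd, fset, clf, fm_cache = cache)
      rows[[length(rows) + 1]] <- results_table(res)
    }
  }
}
results <- do.call(rbind, rows)
write.csv(results, "results/between_srd.csv", row.names = FALSE, quote = FALSE)

# mean CA over test groups and subjects, per training duration
agg <- aggregate(ca ~ srd_train + feature_set + classifier, results, mean)
message("Between-SRD mean CA (%) by training duration:")
print(reshape(agg, direction = "wide", idvar = c("feature_set", "classifier"),
              timevar = "srd_train"), row.names = FALSE)
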
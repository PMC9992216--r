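#!/usr/bin/env Rscript
# Step 5: summarize both scenarios — duration ordering, macro-MCC, Friedman
# rank tests across SRD groups, and per-gesture recognition at the best
# duration — and write the JSON summary.

library(srdemg)

within <- read.csv("results/within_srd.csv")
between <- read.csv("results/between_srd.csv")

summarize <- function(results, label) {
  agg <- aggregate(cbind(ca, mcc_macro) ~ srd_train, results, mean)
  message(sprintf("%s: mean CA over the grid, by training duration:", label))
  print(agg, row.names = FALSE)
  agg
}
w <- summarize(within, "Within-SRD")
b <- summarize(between, "Between-SRD")

best <- b$srd_train[which.max(b$ca)]
message(sprintf("Between-SRD ordering: best training duration %g s; 1 s worst (%0.1f%%); 20 s below 15 s by %0.2f%%",
                best, b$ca[b$srd_train == 1],
                b$ca[b$srd_train == 15] - b$ca[b$srd_train == 20]))

# Friedman: blocks = subjects, treatments = SRD groups, per feature/classifier
fried <- list()
for (fset in unique(between$feature_set)) {
  for (clf in unique(between$classifier)) {
    sub <- between[between$feature_set == fset & between$classifier == clf, ]
    agg <- aggregate(ca ~ subject + srd_train, sub, mean)
    m <- as.matrix(xtabs(ca ~ subject + srd_train, agg))
    if (nrow(m) >= 2) {
      ft <- friedman_test(m)
      fried[[paste(fset, clf, sep = "_")]] <-
        list(statistic = ft$statistic, p_value = ft$p_value)
      message(sprintf("Friedman across SRDs, %s + %s: chi2 = %.2f, p = %.4f",
                      fset, clf, ft$statistic, ft$p_value))
    }
  }
}

jsonlite::write_json(
  list(within_mean_ca = setNames(w$ca, paste0("srd", w$srd_train)),
       between_mean_ca = setNames(b$ca, paste0("srd", b$srd_train)),
       between_mean_mcc = setNames(b$mcc_macro, paste0("srd", b$srd_train)),
       friedman = fried),
  "results/summary.json", auto_unbox = TRUE, digits = NA)
message("wrote results/summary.json")
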
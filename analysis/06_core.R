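#!/usr/bin/env Rscript
# Step 6: core-collection construction — greedy M-strategy (full-coverage
# minimal core) and fixed-intensity local search, an intensity scan over
# 20-35%, and distance-based evaluation (A-NE, E-E, E-NE) on Bray-Curtis.
library(ssrcore)

gx <- read_genalex("results/genotypes.csv")
cm <- mstrategy_core(gx$dataset, seed = 42)
print(cm)
writeLines(cm$ids, "results/core_mstrategy_ids.txt")
scan <- core_intensity_scan(gx$dataset, seed = 42)
write.csv(scan$table, "results/core_intensity_scan.csv", row.names = FALSE)
cat(sprintf("smallest local-search intensity reaching CV = 1: %s\n",
            format(scan$min_full)))
cl <- localsearch_core(gx$dataset, max(scan$min_full, 0.2, na.rm = TRUE),
                       seed = 42)
print(cl)
writeLines(cl$ids, "results/core_localsearch_ids.txt")
evs <- do.call(rbind, lapply(list(cm, cl), function(cs) {
  ev <- evaluate_core(gx$dataset, cs, "bray_curtis")
  data.frame(method = cs$method, N = length(cs$ids),
             pct = round(100 * cs$sampling_intensity, 1), CV = cs$CV,
             A_NE = ev$A_NE, E_E = ev$E_E, E_NE_min = ev$E_NE_min,
             E_NE_mean = ev$E_NE_mean)
}))
write.csv(evs, "results/core_evaluation.csv", row.names = FALSE)
print(evs)
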
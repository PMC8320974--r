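#!/usr/bin/env Rscript
# Step 5: Bayesian admixture scan over K = 1..12 with replicate Gibbs runs
# and Evanno delta-K model selection. Desk-scale MCMC lengths (500 burn-in /
# 1500 sweeps, 3 replicates); raise to 10000/50000 to mirror
# publication-scale settings.
library(ssrcore)

gx <- read_genalex("results/genotypes.csv")
runs <- structure_scan(gx$dataset, 1:12, replicates = 3,
                       burn_in = 500, n_sweeps = 1500, seed = 42)
tab <- evanno_delta_k(runs)
write.csv(tab, "results/evanno.csv", row.names = FALSE)
best_k <- attr(tab, "best_K")
cat("Evanno delta-K table:\n"); print(round(tab, 2))
cat(sprintf("best K = %d\n", best_k))
best <- Filter(function(r) r$K == best_k, runs)[[1]]
write.csv(data.frame(id = rownames(best$Q), round(best$Q, 4),
                     label = assign_clusters(best, 0.8)),
          sprintf("results/q_matrix_K%d.csv", best_k), row.names = FALSE)
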
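#!/usr/bin/env Rscript
# Step 7: validate both core collections against the whole germplasm —
# Welch t-tests on per-locus diversity indices, per-locus chi-square on
# allele counts, allele-frequency R^2, and UPGMA trees of the core entries.
library(ssrcore)

gx <- read_genalex("results/genotypes.csv")
for (nm in c("mstrategy", "localsearch")) {
  ids <- readLines(sprintf("results/core_%s_ids.txt", nm))
  val <- validate_core(gx$dataset, gx$partition, ids)
  cat("==", nm, "core (", length(ids), "entries ) ==\n")
  print(val)
  write.csv(val$t_tests, sprintf("results/validation_t_%s.csv", nm),
            row.names = FALSE)
  write.csv(val$membership, sprintf("results/validation_membership_%s.csv", nm),
            row.names = FALSE)
  if (!is.null(val$tree))
    write_newick(val$tree, sprintf("results/core_upgma_%s.nwk", nm))
}
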
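#!/usr/bin/env Rscript
# Step 3: population differentiation — combined pairwise matrix (Nei's
# standard distance below the diagonal, FST above), island-model gene flow,
# and two-level AMOVA with 999 permutations.
library(ssrcore)

gx <- read_genalex("results/genotypes.csv")
pm <- population_pair_matrix(gx$dataset, gx$partition)
write_pair_matrix(pm, "results/pair_matrix.csv")
s <- pair_matrix_summary(pm)
cat(sprintf("mean pairwise FST = %.3f (range %.3f-%.3f), mean Nei D = %.3f, Nm = %.3f\n",
            s$mean_fst, s$min_fst, s$max_fst, s$mean_nei, s$Nm))
am <- amova(gx$dataset, gx$partition, n_perm = 999, seed = 42)
print(am)
capture.output(print(am), file = "results/amova.txt")
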
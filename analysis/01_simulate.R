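#!/usr/bin/env Rscript
# Step 1: generate the synthetic germplasm emulating the 12-family,
# 107-SSR Nigerian-based field-genebank collection (186 palms; selfed,
# sib-mated and outcrossed families drawn from 8 founder groups), and
# write it in GenAlEx format for the downstream steps.
library(ssrcore)

dir.create("results", showWarnings = FALSE)
sim <- simulate_germplasm(sim_config(seed = 42))
write_genalex(sim$dataset, sim$partition, "results/genotypes.csv",
              title = "synthetic 12-family oil-palm germplasm")
write_structure(sim$dataset, sim$partition, "results/genotypes.str")
jsonlite::write_json(list(pedigree = sim$truth$pedigree),
                     "results/truth.json", auto_unbox = TRUE)
cat(sprintf("simulated %d palms x %d loci in %d families -> results/genotypes.csv\n",
            n_individuals(sim$dataset), n_loci(sim$dataset),
            length(sim$partition$populations)))
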
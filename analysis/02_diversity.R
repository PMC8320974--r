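#!/usr/bin/env Rscript
# Step 2: marker- and population-level diversity statistics
# (A, Ae, PA, I, Ho, He, F, PIC), i.e. the per-locus and per-population
# summary tables of a standard SSR germplasm survey.
library(ssrcore)

gx <- read_genalex("results/genotypes.csv")
lt <- locus_diversity_table(gx$dataset)
pt <- population_diversity(gx$dataset, gx$partition)
write.csv(lt, "results/locus_diversity.csv", row.names = FALSE)
write.csv(pt, "results/population_diversity.csv", row.names = FALSE)
cat(sprintf("markers: mean A = %.2f, mean He = %.3f, mean PIC = %.3f\n",
            mean(lt$A), mean(lt$He), mean(lt$PIC)))
m <- pt[pt$pop == "Mean", ]
cat(sprintf("populations: mean A = %.3f, Ae = %.3f, Ho = %.3f, He = %.3f, F = %.3f; total PA = %d\n",
            m$A, m$Ae, m$Ho, m$He, m$F, m$PA))
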
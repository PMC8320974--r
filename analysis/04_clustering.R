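#!/usr/bin/env Rscript
# Step 4: individual-level clustering — Dice (Nei & Li) distances, UPGMA
# dendrogram exported as Newick, and PCoA of the same distance matrix.
library(ssrcore)

gx <- read_genalex("results/genotypes.csv")
d <- pairwise_distance(gx$dataset, "dice")
write.csv(round(d, 6), "results/dice_distance.csv")
tree <- upgma(d)
write_newick(tree, "results/upgma.nwk")
pc <- pcoa(d)
write.csv(data.frame(id = rownames(pc$coordinates),
                     round(pc$coordinates[, 1:5], 6)),
          "results/pcoa_coordinates.csv", row.names = FALSE)
cat(sprintf("UPGMA tree written (root height %.4f); first two PCoA axes explain %.2f%% + %.2f%% = %.2f%% of variation\n",
            tree$root$height, pc$percent[1], pc$percent[2],
            pc$percent[1] + pc$percent[2]))
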
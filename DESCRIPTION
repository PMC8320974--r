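Package: ssrcore
Title: Genetic Diversity, Population Structure and Core Collections from SSR Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for codominant microsatellite (SSR) surveys of
    field-genebank germplasm. Reads GenAlEx-dialect genotype tables, computes
    per-locus and per-population diversity statistics (A, Ae, PA, I, Ho, He,
    F, PIC), population differentiation (Nei's standard genetic distance,
    pairwise FST, island-model gene flow, two-level AMOVA with permutation
    testing), individual-level clustering (Dice and Bray-Curtis distances,
    UPGMA with Newick export, principal coordinate analysis), Bayesian
    admixture inference by Gibbs sampling with Evanno delta-K model
    selection, and core-collection construction by greedy allele-coverage
    maximization or local search, with distance-based evaluation and
    statistical validation against the whole collection. Includes a
    pedigree-aware synthetic germplasm generator emulating selfed, sib-mated
    and outcrossed families derived from divergent founder groups.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    vegan,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
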